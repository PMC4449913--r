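apple
banana
blackberry
blueberry
cherry
coconut
grape
kiwi
lemon
lime
mango
melon
watermelon
orange
tangerine
papaya
passion fruit
peach
pear
pineapple
pomelo
raspberry
strawberry
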