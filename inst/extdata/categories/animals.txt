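bull
cow
chicken
donkey
goat
horse
pig
rabbit
sheep
dolphin
shark
octopus
turtle
bird
eagle
mouse
owl
bear
bat
dog
cat
fly
ant
tiger
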