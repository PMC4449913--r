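blue
green
red
yellow
orange
black
white
pink
brown
fuchsia
grey
purple
violet
golden
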