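raw,replacement
skky,sky
watter,water
grean,green
bulding,building
mountian,mountain
peeple,people
stret,street
citty,city
forrest,forest
beutiful,beautiful
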