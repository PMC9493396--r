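inflected	base
children	child
walked	walk
walking	walk
walks	walk
ran	run
running	run
runs	run
played	play
playing	play
plays	play
jumped	jump
jumping	jump
jumps	jump
swimming	swim
swims	swim
cats	cat
dogs	dog
trees	tree
clouds	cloud
flowers	flower
buildings	building
mountains	mountain
cars	car
houses	house
birds	bird
rocks	rock
fields	field
streets	street
roads	road
lakes	lake
rivers	river
oceans	ocean
beaches	beach
animals	animal
colors	color
days	day
nights	night
lights	light
letters	letter
words	word
boats	boat
bridges	bridge
men	man
women	woman
skies	sky
grasses	grass
forests	forest
landscapes	landscape
mornings	morning
evenings	evening
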