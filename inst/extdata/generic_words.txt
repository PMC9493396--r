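sky
water
tree
grass
cloud
sun
light
dark
blue
green
red
white
black
bright
outdoor
indoor
nature
city
street
building
people
bridge
man
woman
child
house
road
car
field
mountain
river
lake
ocean
beach
sand
rock
forest
flower
animal
bird
dog
cat
day
night
color
big
small
old
new
open
calm
quiet
busy
cold
warm
summer
winter
morning
evening
landscape
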