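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
walk
run
play
jump
swim
beautiful
exciting
ball
apple
letter
text
word
boat
speedboat
crane
drill
skyscraper
tall
natural
sea
wave
boats
na
none
arbitrary
nothing
blank
dunno
children
walked
walking
walks
ran
running
runs
played
playing
plays
jumped
jumping
jumps
swimming
swims
cats
dogs
trees
clouds
flowers
buildings
mountains
cars
houses
birds
rocks
fields
streets
roads
lakes
rivers
oceans
beaches
animals
colors
days
nights
lights
letters
words
bridges
men
women
skies
grasses
forests
landscapes
mornings
evenings
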