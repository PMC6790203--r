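hay
fever
hayfever
pollen
sneeze
sneezing
allergy
allergies
spring
season
today
morning
weather
nose
eyes
itchy
grass
garden
outside
melbourne
sydney
australia
windy
summer
week
time
people
really
feeling
literally
honestly
actually
going
know
love
hate
worse
worst
good
high
count
night
back
still
everyone
another
year
start
air
bad
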