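parliament
bottle
football
coffee
movie
music
party
birthday
holiday
school
office
traffic
dinner
pizza
phone
games
episode
netflix
beach
shopping
friends
puppy
kitten
guitar
homework
painting
concert
ticket
garage
recipe
baking
cricket
winning
random
joke
simply
horse
paddock
farmer
meadow
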