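kicking
struggling
suffering
annoying
dying
ruining
driving
crazy
nightmare
attack
acting
flaring
playing
killing
sleep
awake
tired
exhausted
moody
ruined
weekend
sunday
monday
lovely
wanted
telling
differently
sobbing
crying
whinge
grumpy
sniffles
tickle
brutal
savage
defeated
done
agony
misery
cursed
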