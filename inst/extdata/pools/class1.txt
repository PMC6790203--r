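watering
watery
burning
streaming
blocked
runny
congested
congestion
coughing
wheezing
headache
sinus
sinuses
throat
scratchy
swollen
puffy
tissues
antihistamine
antihistamines
medication
nasal
spray
drops
tablets
claratyne
telfast
zyrtec
pharmacy
doctor
prescribed
dosage
symptoms
miserable
sniffling
constant
itching
inflamed
drowsy
asthma
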