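treatment
forecast
warning
alert
report
research
study
experts
breaking
update
launch
product
offer
discount
sale
available
online
clinic
survey
campaign
awareness
advice
tips
guide
protect
prevention
breakthrough
scientists
million
percent
increase
surge
levels
extreme
danger
thunderstorm
health
service
patients
readers
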