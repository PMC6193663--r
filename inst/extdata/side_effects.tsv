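category	term
urinary	leakage
urinary	leak
urinary	leaking
urinary	drip
urinary	dripping
urinary	dribbling
urinary	incontinence
urinary	pads
sexual	ed
sexual	impotence
sexual	erection
sexual	erections
sexual	erectile dysfunction
bowel	diarrhea
bowel	diarrhoea
bowel	urgency
bowel	rectal bleeding
bowel	loose stools
other	hernia
other	clot
other	clots
other	blood clot
other	infection
other	infections
other	bleeding
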