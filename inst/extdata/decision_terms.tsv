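role	term
decide	decided
decide	chosen
decide	chose
decide	wind up going
decide	made the call
decide	settled
decide	opted
decide	went for
decide	took the option
decide	end up
recommend	recommend
recommend	recommended
recommend	prescribe
recommend	prescribed
recommend	advised
recommend	advise
recommend	endorse
recommend	endorsed
recommend	advocate
doctor	doctor
doctor	doc
doctor	surgeon
doctor	urologist
doctor	uro
doctor	specialist
doctor	consultant
doctor	radiologist
doctor	oncologist
doctor	radiotherapist
treatment:Surgery	surgery
treatment:Surgery	davinci
treatment:Surgery	da vinci
treatment:Surgery	robotic
treatment:Surgery	prostatectomy
treatment:Surgery	ralp
treatment:Surgery	rrp
treatment:Surgery	lrp
treatment:Surgery	rpp
treatment:Surgery	key hole
treatment:Surgery	open op
treatment:Radiation	radiation
treatment:Radiation	imrt
treatment:Radiation	brachytherapy
treatment:Radiation	radiotherapy
treatment:Radiation	seed therapy
treatment:Radiation	brachy
treatment:Radiation	seed implant
treatment:Radiation	ebrt
treatment:Surveillance	surveillance
treatment:Surveillance	active surveillance
treatment:Surveillance	watch and wait
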