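factor	term
doctor experience	experience
doctor experience	experienced
doctor experience	track record
doctor experience	reputation
doctor experience	skilled hands
side effects	side effects
side effects	side effect
best cancer control	cancer control
best cancer control	best chance of cure
best cancer control	cure rates
best cancer control	get it all out
age	my age
age	at my age
fast recovery	fast recovery
fast recovery	quick recovery
fast recovery	recovery time
fast recovery	back on my feet
financial concerns	insurance
financial concerns	out of pocket
financial concerns	cost
financial concerns	expensive
financial concerns	afford
bowel symptoms	bowel symptoms
bowel symptoms	bowel issues
bowel symptoms	bowel problems
radiation oncologist	radiation oncologist
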