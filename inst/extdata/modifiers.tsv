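role	term
booster	very
booster	really
booster	extremely
booster	so
booster	absolutely
booster	incredibly
booster	completely
booster	totally
booster	utterly
booster	especially
booster	particularly
booster	deeply
booster	hugely
booster	immensely
booster	exceptionally
booster	truly
booster	tremendously
dampener	somewhat
dampener	slightly
dampener	barely
dampener	hardly
dampener	marginally
dampener	scarcely
dampener	kinda
dampener	sorta
dampener	kind of
dampener	sort of
dampener	a little
dampener	a bit
dampener	a tad
dampener	mildly
dampener	moderately
negator	not
negator	never
negator	no
negator	none
negator	nothing
negator	neither
negator	nobody
negator	didn't
negator	don't
negator	doesn't
negator	isn't
negator	wasn't
negator	aren't
negator	weren't
negator	won't
negator	wouldn't
negator	can't
negator	cannot
negator	couldn't
negator	shouldn't
negator	hasn't
negator	haven't
negator	hadn't
negator	ain't
negator	without
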