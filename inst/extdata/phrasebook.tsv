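kind	text
filler	the weather has been mild this week.
filler	thanks to everyone who replied earlier.
filler	my appointment is on thursday.
filler	i spent the weekend in the garden.
filler	the drive to the clinic takes about an hour.
filler	reading through old threads here.
filler	my wife came along to the consult.
filler	the nurse called with the lab times.
filler	we walked along the river on sunday.
filler	the forum has been quiet lately.
filler	i keep a small notebook of questions.
filler	the hospital parking was full again.
filler	my follow up is booked for next month.
filler	the garden needs attention this time of year.
filler	i listened to the radio most of the evening.
filler	the waiting room was crowded today.
filler	we had family visiting over the weekend.
filler	i took the dog for a long walk.
filler	the paperwork from the clinic finally arrived.
filler	dinner with friends was a welcome distraction.
question	has anyone else been through this stage?
question	what did others find useful at this point?
question	how long did the first review take?
question	is there anything i have missed here?
question	where did everyone start with the reading?
advice	you should ask your doctor about this.
advice	you could try keeping a simple diary.
advice	you should ask the team about timing.
emotion_carrier	i have felt {term} lately.
emotion_carrier	feeling {term} these days.
side_effect_carrier	dealing with {term} since the treatment.
side_effect_carrier	the {term} has been a nuisance this month.
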