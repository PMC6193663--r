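category	term	provenance
Happy	happy	seed
Happy	great	seed
Happy	joyous	seed
Happy	glad	seed
Happy	delighted	seed
Happy	fab	expanded-accepted
Happy	chuffed	expanded-accepted
Happy	terrific	expanded-accepted
Happy	great news	expanded-accepted
Happy	looking forward	expanded-accepted
Happy	heart warming	expanded-accepted
Happy	uplifting	expanded-accepted
Happy	upbeat	expanded-accepted
Good	good	seed
Good	pleased	seed
Good	comfortable	seed
Good	relaxed	seed
Good	content	seed
Good	comfy	expanded-accepted
Good	nice	expanded-accepted
Good	chill	expanded-accepted
Good	chipper	expanded-accepted
Good	ok	expanded-accepted
Good	okay	expanded-accepted
Good	clear headed	expanded-accepted
Good	cool	expanded-accepted
Alive	alive	seed
Alive	playful	seed
Alive	energetic	seed
Alive	spirited	seed
Alive	animated	seed
Alive	chatty	expanded-accepted
Alive	perky	expanded-accepted
Alive	sociable	expanded-accepted
Alive	vibrant	expanded-accepted
Alive	vivacious	expanded-accepted
Alive	witty	expanded-accepted
Alive	easy going	expanded-accepted
Alive	peppy	expanded-accepted
Love	love	seed
Love	attracted	seed
Love	warm	seed
Love	passionate	seed
Love	affectionate	seed
Love	romantic	expanded-accepted
Love	cuddly	expanded-accepted
Love	compassionate	expanded-accepted
Love	intimate	expanded-accepted
Love	adore	expanded-accepted
Love	supportive	expanded-accepted
Love	caring	expanded-accepted
Positive	positive	seed
Positive	eager	seed
Positive	keen	seed
Positive	bold	seed
Positive	brave	seed
Positive	smart	expanded-accepted
Positive	ambitious	expanded-accepted
Positive	proactive	expanded-accepted
Positive	cynical	expanded-accepted
Positive	insistent	expanded-accepted
Positive	upbeat	expanded-accepted
Positive	willing	expanded-accepted
Open	open	seed
Open	understanding	seed
Open	accepting	seed
Open	satisfied	seed
Open	receptive	seed
Open	open minded	expanded-accepted
Open	empathetic	expanded-accepted
Open	cooperative	expanded-accepted
Open	accommodating	expanded-accepted
Open	approachable	expanded-accepted
Open	forgiving	expanded-accepted
Open	attuned	expanded-accepted
Open	rational	expanded-accepted
Interested	interested	seed
Interested	fascinated	seed
Interested	inquisitive	seed
Interested	curious	seed
Interested	intrigued	seed
Interested	keen	expanded-accepted
Interested	impressed	expanded-accepted
Interested	eager	expanded-accepted
Interested	cautious	expanded-accepted
Interested	leery	expanded-accepted
Interested	intuitive	expanded-accepted
Interested	savvy	expanded-accepted
Interested	thoughtful	expanded-accepted
Strong	strong	seed
Strong	certain	seed
Strong	dynamic	seed
Strong	sure	seed
Strong	tenacious	seed
Strong	resilient	expanded-accepted
Strong	independent	expanded-accepted
Strong	adamant	expanded-accepted
Strong	fierce	expanded-accepted
Strong	self reliant	expanded-accepted
Strong	decisive	expanded-accepted
Strong	fighter	expanded-accepted
Strong	pragmatic	expanded-accepted
Sad	sad	seed
Sad	tearful	seed
Sad	grief	seed
Sad	sorrowful	seed
Sad	heart break	expanded-accepted
Sad	teary	expanded-accepted
Sad	lonely	expanded-accepted
Sad	weepy	expanded-accepted
Sad	crying	expanded-accepted
Sad	despairing	expanded-accepted
Sad	hurtful	expanded-accepted
Afraid	afraid	seed
Afraid	fearful	seed
Afraid	terrified	seed
Afraid	panic	seed
Afraid	worry	seed
Afraid	petrified	expanded-accepted
Afraid	freaking out	expanded-accepted
Afraid	apprehensive	expanded-accepted
Afraid	dread	expanded-accepted
Afraid	obsess	expanded-accepted
Afraid	fret	expanded-accepted
Afraid	nervous wreck	expanded-accepted
Hurt	hurt	seed
Hurt	deprived	seed
Hurt	pained	seed
Hurt	dejected	seed
Hurt	agonised	seed
Hurt	traumatised	expanded-accepted
Hurt	bruised	expanded-accepted
Hurt	shattered	expanded-accepted
Hurt	ached	expanded-accepted
Hurt	exhausted	expanded-accepted
Hurt	cramped	expanded-accepted
Hurt	numb	expanded-accepted
Hurt	fatigued	expanded-accepted
Hurt	strained	expanded-accepted
Angry	angry	seed
Angry	annoy	seed
Angry	provoke	seed
Angry	aggressive	seed
Angry	enraged	seed
Angry	agitated	expanded-accepted
Angry	hostile	expanded-accepted
Angry	pissed off	expanded-accepted
Angry	argumentative	expanded-accepted
Angry	rude	expanded-accepted
Angry	paranoid	expanded-accepted
Angry	ticked off	expanded-accepted
Angry	lashing out	expanded-accepted
Depressed	depressed	seed
Depressed	disappointed	seed
Depressed	miserable	seed
Depressed	despair	seed
Depressed	powerless	seed
Depressed	despondent	expanded-accepted
Depressed	distraught	expanded-accepted
Depressed	suicidal	expanded-accepted
Depressed	unloved	expanded-accepted
Depressed	worthless	expanded-accepted
Depressed	emotionally drained	expanded-accepted
Depressed	snappy	expanded-accepted
Helpless	helpless	seed
Helpless	incapable	seed
Helpless	alone	seed
Helpless	vulnerable	seed
Helpless	fatigued	seed
Helpless	insecure	expanded-accepted
Helpless	tired	expanded-accepted
Helpless	hopeless	expanded-accepted
Helpless	powerless	expanded-accepted
Helpless	defeated	expanded-accepted
Helpless	overwhelmed	expanded-accepted
Helpless	listless	expanded-accepted
Helpless	incapacitated	expanded-accepted
Confused	confused	seed
Confused	upset	seed
Confused	doubtful	seed
Confused	uncertain	seed
Confused	hesitant	seed
Confused	unsure	expanded-accepted
Confused	perplexed	expanded-accepted
Confused	wary	expanded-accepted
Confused	leery	expanded-accepted
Confused	freaked out	expanded-accepted
Confused	iffy	expanded-accepted
Confused	bummed	expanded-accepted
Confused	taken aback	expanded-accepted
Indifferent	indifferent	seed
Indifferent	insensitive	seed
Indifferent	dull	seed
Indifferent	reserved	seed
Indifferent	lifeless	seed
Indifferent	grumpy	expanded-accepted
Indifferent	apathetic	expanded-accepted
Indifferent	blunt	expanded-accepted
Indifferent	ignorant	expanded-accepted
Indifferent	emotionless	expanded-accepted
Indifferent	callous	expanded-accepted
Indifferent	crass	expanded-accepted
Indifferent	standoffish	expanded-accepted
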