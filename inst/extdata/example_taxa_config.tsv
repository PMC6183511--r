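genus	species	button	button label	category	recognition name
Antarctissa	strelkovi	yes	Astr	Plagiacanthidae	antarctissa strelkovi
Antarctissa	denticulata	yes	Aden	Plagiacanthidae	antarctissa denticulata
Cycladophora	davisiana	yes	Cdav	Theopiliidae	cycladophora davisiana
Lithomelissa	setosa	no		Plagiacanthidae	lithomelissa setosa
Spongotrochus	glacialis	no		Spongodiscidae	spongotrochus glacialis
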