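file_type	version	block	key	label	required
O	1	file	version	SOD version	TRUE
O	1	file	file_type	File type	TRUE
O	1	file	leg	Leg	FALSE
O	1	file	site	Site	TRUE
O	1	file	hole	Hole	TRUE
O	1	file	latitude	Latitude	FALSE
O	1	file	longitude	Longitude	FALSE
O	1	file	ocean	Ocean	FALSE
O	1	file	fossil_group	Fossil group	FALSE
O	1	file	observer	Observer	FALSE
O	1	file	date	Date	FALSE
O	1	file	source	Source	FALSE
O	1	sample	sample_id	Sample ID	TRUE
O	1	sample	core	Core	FALSE
O	1	sample	section	Section	FALSE
O	1	sample	interval	Interval	FALSE
O	1	sample	depth	Depth (mbsf)	FALSE
O	1	sample	zone	Zone	FALSE
O	1	sample	age	Age (Ma)	FALSE
O	1	sample	tracks_full	Tracks full	FALSE
O	1	sample	tracks_rare	Tracks rare	FALSE
O	1	sample	threshold	Exclusion threshold	FALSE
O	1	sample	excluded_taxa	Excluded taxa	FALSE
L	1	file	version	SOD version	TRUE
L	1	file	file_type	File type	TRUE
L	1	file	region	Region	FALSE
L	1	file	section	Section	TRUE
L	1	file	latitude	Latitude	FALSE
L	1	file	longitude	Longitude	FALSE
L	1	file	formation	Formation	FALSE
L	1	file	lithology	Lithology	FALSE
L	1	file	fossil_group	Fossil group	FALSE
L	1	file	observer	Observer	FALSE
L	1	file	date	Date	FALSE
L	1	file	source	Source	FALSE
L	1	sample	sample_id	Sample name	TRUE
L	1	sample	level	Level (m)	FALSE
L	1	sample	zone	Zone	FALSE
L	1	sample	age	Age (Ma)	FALSE
L	1	sample	tracks_full	Tracks full	FALSE
L	1	sample	tracks_rare	Tracks rare	FALSE
L	1	sample	threshold	Exclusion threshold	FALSE
L	1	sample	excluded_taxa	Excluded taxa	FALSE
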