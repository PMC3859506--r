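sample	Archaea	Bacteria	Eukaryota	Mixed	Viruses	Other	Unclassified	Total
NY_INDOOR	1048	256691	663225	6012	958	1084	504660	1433678
NY_OUTDOOR	269	55681	281601	1915	495	1389	620628	961978
SD_IHOSP	286	347562	68998	5975	1926	491	152468	577706
SD_OHOSP	606	263396	167883	7010	514	167	384538	824114
SD_IHOUS	90	192326	40334	5936	4186	206	148683	391761
SD_SCRPP	324	44092	375198	2356	2026	67	729639	1153702
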