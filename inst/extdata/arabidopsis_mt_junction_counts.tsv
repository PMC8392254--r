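intron_id	splice_type	mechanism	n_ei5	n_i3e	n_ee
ccmFci	cis	branching	192	356	1149
cox2i	cis	branching	129	282	12433
nad1i1	trans	hydrolytic	180	1197	944
nad1i2	cis	hydrolytic	151	174	2322
nad1i3	trans	both	187	945	3210
nad1i4	cis	branching	240	1280	1982
nad2i1	cis	hydrolytic	141	437	919
nad2i2	trans	branching	54	476	1958
nad2i3	cis	branching	59	581	1471
nad2i4	cis	branching	389	460	2688
nad4i1	cis	both	480	633	2498
nad4i2	cis	hydrolytic	144	125	6924
nad4i3	cis	branching	163	468	8402
nad5i1	cis	branching	278	817	1452
nad5i4	cis	branching	189	1031	17008
nad7i1	cis	hydrolytic	75	135	639
nad7i2	cis	branching	177	1379	1169
nad7i3	cis	branching	104	332	4001
nad7i4	cis	branching	209	304	2685
rpl2i	cis	both	122	685	465
rps3i	cis	branching	496	211	734
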