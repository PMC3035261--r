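method	algorithm	formula	threshold	error_ratio	intercept	slope
ncbi-blast	trimming	1	0.2676	0.0860	96.8979	-121.4848
ncbi-blast	trimming	2	0.0412	0.0430	90.3998	-438.3134
ncbi-blast	trimming	3	0.2945	0.0860	98.6313	-118.8770
wu-blast	trimming	1	0.0436	0.2796	122.9402	-406.2128
wu-blast	trimming	2	0.0870	0.0430	82.1068	-166.2293
wu-blast	trimming	3	0.2870	0.0860	115.4105	-191.9086
blat	trimming	1	0.2672	0.0753	97.7166	-127.9852
blat	trimming	2	0.0416	0.0430	87.0748	-376.3038
blat	trimming	3	0.2811	0.0645	100.6280	-122.5151
blastz	trimming	1	0.2389	0.2043	89.8757	-102.0887
blastz	trimming	2	0.0575	0.0538	85.1650	-273.1803
blastz	trimming	3	0.3344	0.1828	111.9235	-125.1989
mummer	coverage	1	0.6110	0.0430	130.9618	-116.4258
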