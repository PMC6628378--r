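type	HRK0-1	HRK0-2	HRK48-1	HRK48-2	HSK0-1	HSK0-2	HSK48-1	HSK48-2
Total reads	18187564	15645006	15811473	22213829	15877691	16418090	19154749	19705533
Clean reads	16725511(91.96%)	14594887(93.29%)	14335242(90.66%)	20230796(91.07%)	14697929(92.57%)	15060199(91.73%)	17541500(91.58%)	18523834(94.00%)
Mapped reads	15092682(90.24%)	13055191(89.45%)	12999357(90.68%)	18078009(89.36%)	13090959(89.07%)	13620528(90.44%)	15751832(89.80%)	16892630(91.19%)
Intergenic	9443266(56.46%)	7076994(48.49%)	7502556(52.34%)	10774382(53.26%)	8035260(54.67%)	7314000(48.57%)	9032395(51.49%)	9351270(50.48%)
Exon	2296806(13.73%)	2735655(18.74%)	2230122(15.56%)	3074662(15.20%)	2018611(13.73%)	2881758(19.13%)	2785970(15.88%)	3185485(17.20%)
Intron	2197086(13.14%)	2293967(15.72%)	2330038(16.25%)	2958235(14.62%)	2056682(13.99%)	2628373(17.45%)	2986540(17.03%)	3410640(18.41%)
miRNA	929540(5.56%)	607305(4.16%)	536353(3.74%)	959353(4.74%)	748416(5.09%)	528713(3.51%)	641115(3.65%)	584366(3.15%)
rRNA	211127(1.26%)	345408(2.37%)	395420(2.76%)	295084(1.46%)	233612(1.59%)	262057(1.74%)	294055(1.68%)	346254(1.87%)
snoRNA	5719(0.03%)	6779(0.05%)	5929(0.04%)	9232(0.05%)	4486(0.03%)	6169(0.04%)	7500(0.04%)	8553(0.05%)
tRNA	1767(0.01%)	2581(0.02%)	5226(0.04%)	6462(0.03%)	1742(0.01%)	1970(0.01%)	1915(0.07%)	3580(0.02%)
sncRNA	4662(0.03%)	5472(0.04%)	7182(0.05%)	7141(0.04%)	5164(0.04%)	5714(0.04%)	5719(0.03%)	5406(0.03%)
Precursor	30472(0.18%)	7206(0.05%)	6290(0.04%)	34022(0.17%)	5193(0.04%)	7113(0.05%)	2449(0.01%)	51321(0.28%)
Unmap	1604212(9.59%)	1518313(10.40%)	1312486(9.17%)	2110698(10.43%)	1588107(10.80%)	1423625(9.45%)	1771428(10.10%)	1574369(8.50%)
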