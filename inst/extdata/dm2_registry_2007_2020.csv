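year,cohort,males,females,positives
2020,30,14,16,7
2019,52,27,25,22
2018,56,22,34,18
2017,57,34,23,11
2016,63,27,36,23
2015,49,19,30,14
2014,40,20,20,14
2013,20,7,13,8
2012,39,21,18,17
2011,42,23,19,13
2010,35,19,16,12
2009,34,21,13,11
2008,40,22,18,14
2007,13,8,5,3
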