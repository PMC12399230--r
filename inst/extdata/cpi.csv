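year,deflator_to_2022
2010,1.4080
2011,1.3665
2012,1.3182
2013,1.2865
2014,1.2565
2015,1.2242
2016,1.1796
2017,1.1507
2018,1.1284
2019,1.0973
2020,1.0540
2021,1.0399
2022,1.0000
2023,0.9803
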