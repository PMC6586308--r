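# NIH/3T3 allele calls by 12 consortium laboratories at 18
# mouse STR markers; lab L04 misses allele 20.3 at marker 4-2.
cell_line,lab_id,marker,alleles
NIH/3T3,L01,18-3,17;19
NIH/3T3,L01,4-2,19.3;20.3
NIH/3T3,L01,6-7,12
NIH/3T3,L01,19-2,11;12
NIH/3T3,L01,1-2,13;17
NIH/3T3,L01,7-1,29
NIH/3T3,L01,1-1,10
NIH/3T3,L01,3-2,14;15
NIH/3T3,L01,8-1,15
NIH/3T3,L01,2-1,9
NIH/3T3,L01,15-3,20.3
NIH/3T3,L01,6-4,15.3
NIH/3T3,L01,11-2,15;17
NIH/3T3,L01,17-2,13;14
NIH/3T3,L01,12-1,20
NIH/3T3,L01,5-5,14;15
NIH/3T3,L01,X-1,25
NIH/3T3,L01,13-1,16.2
NIH/3T3,L02,18-3,17;19
NIH/3T3,L02,4-2,19.3;20.3
NIH/3T3,L02,6-7,12
NIH/3T3,L02,19-2,11;12
NIH/3T3,L02,1-2,13;17
NIH/3T3,L02,7-1,29
NIH/3T3,L02,1-1,10
NIH/3T3,L02,3-2,14;15
NIH/3T3,L02,8-1,15
NIH/3T3,L02,2-1,9
NIH/3T3,L02,15-3,20.3
NIH/3T3,L02,6-4,15.3
NIH/3T3,L02,11-2,15;17
NIH/3T3,L02,17-2,13;14
NIH/3T3,L02,12-1,20
NIH/3T3,L02,5-5,14;15
NIH/3T3,L02,X-1,25
NIH/3T3,L02,13-1,16.2
NIH/3T3,L03,18-3,17;19
NIH/3T3,L03,4-2,19.3;20.3
NIH/3T3,L03,6-7,12
NIH/3T3,L03,19-2,11;12
NIH/3T3,L03,1-2,13;17
NIH/3T3,L03,7-1,29
NIH/3T3,L03,1-1,10
NIH/3T3,L03,3-2,14;15
NIH/3T3,L03,8-1,15
NIH/3T3,L03,2-1,9
NIH/3T3,L03,15-3,20.3
NIH/3T3,L03,6-4,15.3
NIH/3T3,L03,11-2,15;17
NIH/3T3,L03,17-2,13;14
NIH/3T3,L03,12-1,20
NIH/3T3,L03,5-5,14;15
NIH/3T3,L03,X-1,25
NIH/3T3,L03,13-1,16.2
NIH/3T3,L04,18-3,17;19
NIH/3T3,L04,4-2,19.3
NIH/3T3,L04,6-7,12
NIH/3T3,L04,19-2,11;12
NIH/3T3,L04,1-2,13;17
NIH/3T3,L04,7-1,29
NIH/3T3,L04,1-1,10
NIH/3T3,L04,3-2,14;15
NIH/3T3,L04,8-1,15
NIH/3T3,L04,2-1,9
NIH/3T3,L04,15-3,20.3
NIH/3T3,L04,6-4,15.3
NIH/3T3,L04,11-2,15;17
NIH/3T3,L04,17-2,13;14
NIH/3T3,L04,12-1,20
NIH/3T3,L04,5-5,14;15
NIH/3T3,L04,X-1,25
NIH/3T3,L04,13-1,16.2
NIH/3T3,L05,18-3,17;19
NIH/3T3,L05,4-2,19.3;20.3
NIH/3T3,L05,6-7,12
NIH/3T3,L05,19-2,11;12
NIH/3T3,L05,1-2,13;17
NIH/3T3,L05,7-1,29
NIH/3T3,L05,1-1,10
NIH/3T3,L05,3-2,14;15
NIH/3T3,L05,8-1,15
NIH/3T3,L05,2-1,9
NIH/3T3,L05,15-3,20.3
NIH/3T3,L05,6-4,15.3
NIH/3T3,L05,11-2,15;17
NIH/3T3,L05,17-2,13;14
NIH/3T3,L05,12-1,20
NIH/3T3,L05,5-5,14;15
NIH/3T3,L05,X-1,25
NIH/3T3,L05,13-1,16.2
NIH/3T3,L06,18-3,17;19
NIH/3T3,L06,4-2,19.3;20.3
NIH/3T3,L06,6-7,12
NIH/3T3,L06,19-2,11;12
NIH/3T3,L06,1-2,13;17
NIH/3T3,L06,7-1,29
NIH/3T3,L06,1-1,10
NIH/3T3,L06,3-2,14;15
NIH/3T3,L06,8-1,15
NIH/3T3,L06,2-1,9
NIH/3T3,L06,15-3,20.3
NIH/3T3,L06,6-4,15.3
NIH/3T3,L06,11-2,15;17
NIH/3T3,L06,17-2,13;14
NIH/3T3,L06,12-1,20
NIH/3T3,L06,5-5,14;15
NIH/3T3,L06,X-1,25
NIH/3T3,L06,13-1,16.2
NIH/3T3,L07,18-3,17;19
NIH/3T3,L07,4-2,19.3;20.3
NIH/3T3,L07,6-7,12
NIH/3T3,L07,19-2,11;12
NIH/3T3,L07,1-2,13;17
NIH/3T3,L07,7-1,29
NIH/3T3,L07,1-1,10
NIH/3T3,L07,3-2,14;15
NIH/3T3,L07,8-1,15
NIH/3T3,L07,2-1,9
NIH/3T3,L07,15-3,20.3
NIH/3T3,L07,6-4,15.3
NIH/3T3,L07,11-2,15;17
NIH/3T3,L07,17-2,13;14
NIH/3T3,L07,12-1,20
NIH/3T3,L07,5-5,14;15
NIH/3T3,L07,X-1,25
NIH/3T3,L07,13-1,16.2
NIH/3T3,L08,18-3,17;19
NIH/3T3,L08,4-2,19.3;20.3
NIH/3T3,L08,6-7,12
NIH/3T3,L08,19-2,11;12
NIH/3T3,L08,1-2,13;17
NIH/3T3,L08,7-1,29
NIH/3T3,L08,1-1,10
NIH/3T3,L08,3-2,14;15
NIH/3T3,L08,8-1,15
NIH/3T3,L08,2-1,9
NIH/3T3,L08,15-3,20.3
NIH/3T3,L08,6-4,15.3
NIH/3T3,L08,11-2,15;17
NIH/3T3,L08,17-2,13;14
NIH/3T3,L08,12-1,20
NIH/3T3,L08,5-5,14;15
NIH/3T3,L08,X-1,25
NIH/3T3,L08,13-1,16.2
NIH/3T3,L09,18-3,17;19
NIH/3T3,L09,4-2,19.3;20.3
NIH/3T3,L09,6-7,12
NIH/3T3,L09,19-2,11;12
NIH/3T3,L09,1-2,13;17
NIH/3T3,L09,7-1,29
NIH/3T3,L09,1-1,10
NIH/3T3,L09,3-2,14;15
NIH/3T3,L09,8-1,15
NIH/3T3,L09,2-1,9
NIH/3T3,L09,15-3,20.3
NIH/3T3,L09,6-4,15.3
NIH/3T3,L09,11-2,15;17
NIH/3T3,L09,17-2,13;14
NIH/3T3,L09,12-1,20
NIH/3T3,L09,5-5,14;15
NIH/3T3,L09,X-1,25
NIH/3T3,L09,13-1,16.2
NIH/3T3,L10,18-3,17;19
NIH/3T3,L10,4-2,19.3;20.3
NIH/3T3,L10,6-7,12
NIH/3T3,L10,19-2,11;12
NIH/3T3,L10,1-2,13;17
NIH/3T3,L10,7-1,29
NIH/3T3,L10,1-1,10
NIH/3T3,L10,3-2,14;15
NIH/3T3,L10,8-1,15
NIH/3T3,L10,2-1,9
NIH/3T3,L10,15-3,20.3
NIH/3T3,L10,6-4,15.3
NIH/3T3,L10,11-2,15;17
NIH/3T3,L10,17-2,13;14
NIH/3T3,L10,12-1,20
NIH/3T3,L10,5-5,14;15
NIH/3T3,L10,X-1,25
NIH/3T3,L10,13-1,16.2
NIH/3T3,L11,18-3,17;19
NIH/3T3,L11,4-2,19.3;20.3
NIH/3T3,L11,6-7,12
NIH/3T3,L11,19-2,11;12
NIH/3T3,L11,1-2,13;17
NIH/3T3,L11,7-1,29
NIH/3T3,L11,1-1,10
NIH/3T3,L11,3-2,14;15
NIH/3T3,L11,8-1,15
NIH/3T3,L11,2-1,9
NIH/3T3,L11,15-3,20.3
NIH/3T3,L11,6-4,15.3
NIH/3T3,L11,11-2,15;17
NIH/3T3,L11,17-2,13;14
NIH/3T3,L11,12-1,20
NIH/3T3,L11,5-5,14;15
NIH/3T3,L11,X-1,25
NIH/3T3,L11,13-1,16.2
NIH/3T3,L12,18-3,17;19
NIH/3T3,L12,4-2,19.3;20.3
NIH/3T3,L12,6-7,12
NIH/3T3,L12,19-2,11;12
NIH/3T3,L12,1-2,13;17
NIH/3T3,L12,7-1,29
NIH/3T3,L12,1-1,10
NIH/3T3,L12,3-2,14;15
NIH/3T3,L12,8-1,15
NIH/3T3,L12,2-1,9
NIH/3T3,L12,15-3,20.3
NIH/3T3,L12,6-4,15.3
NIH/3T3,L12,11-2,15;17
NIH/3T3,L12,17-2,13;14
NIH/3T3,L12,12-1,20
NIH/3T3,L12,5-5,14;15
NIH/3T3,L12,X-1,25
NIH/3T3,L12,13-1,16.2
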