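slice,threshold,tp,tp_uncertain,fp,fn,fn_uncertain,best_without,best_with
29,0.970,11,1,6,12,15,FALSE,FALSE
29,0.955,13,8,13,10,8,FALSE,TRUE
29,0.960,13,3,8,10,13,TRUE,FALSE
30,0.970,16,2,4,10,12,FALSE,TRUE
30,0.965,19,2,9,7,12,TRUE,FALSE
31,0.970,17,1,5,8,6,TRUE,TRUE
32,0.970,11,1,2,16,5,FALSE,FALSE
32,0.960,16,1,6,11,5,TRUE,TRUE
33,0.970,19,2,4,14,6,TRUE,TRUE
34,0.970,17,1,4,31,9,FALSE,FALSE
34,0.945,34,6,30,14,4,TRUE,TRUE
35,0.970,25,2,14,14,10,TRUE,TRUE
36,0.970,27,2,20,8,11,FALSE,TRUE
36,0.980,19,0,2,16,13,TRUE,FALSE
37,0.970,27,2,7,22,9,TRUE,TRUE
38,0.970,10,0,1,44,23,FALSE,FALSE
38,0.945,31,5,26,23,19,FALSE,TRUE
38,0.950,28,2,15,26,21,TRUE,FALSE
39,0.970,25,1,13,30,19,TRUE,FALSE
39,0.965,32,6,33,23,14,FALSE,TRUE
40,0.970,31,1,24,27,20,FALSE,FALSE
40,0.965,38,3,42,20,18,TRUE,TRUE
45,0.970,19,1,19,34,12,TRUE,TRUE
50,0.970,20,2,69,49,4,FALSE,TRUE
50,0.975,17,1,47,52,5,TRUE,FALSE
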