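dimension,level,decrement
intercept,0,1.000
mobility,1,0.000
mobility,2,0.054
mobility,3,0.071
mobility,4,0.206
mobility,5,0.273
self_care,1,0.000
self_care,2,0.048
self_care,3,0.076
self_care,4,0.163
self_care,5,0.202
usual_activities,1,0.000
usual_activities,2,0.047
usual_activities,3,0.060
usual_activities,4,0.160
usual_activities,5,0.183
pain_discomfort,1,0.000
pain_discomfort,2,0.060
pain_discomfort,3,0.080
pain_discomfort,4,0.274
pain_discomfort,5,0.334
anxiety_depression,1,0.000
anxiety_depression,2,0.073
anxiety_depression,3,0.098
anxiety_depression,4,0.283
anxiety_depression,5,0.288
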