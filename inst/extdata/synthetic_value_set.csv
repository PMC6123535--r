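"dimension","level","decrement"
"mobility",1,0
"mobility",2,0.035
"mobility",3,0.057
"mobility",4,0.153
"mobility",5,0.262
"self_care",1,0
"self_care",2,0.036
"self_care",3,0.061
"self_care",4,0.145
"self_care",5,0.244
"usual_activities",1,0
"usual_activities",2,0.039
"usual_activities",3,0.06
"usual_activities",4,0.137
"usual_activities",5,0.26
"pain_discomfort",1,0
"pain_discomfort",2,0.046
"pain_discomfort",3,0.072
"pain_discomfort",4,0.175
"pain_discomfort",5,0.33
"anxiety_depression",1,0
"anxiety_depression",2,0.052
"anxiety_depression",3,0.08
"anxiety_depression",4,0.189
"anxiety_depression",5,0.35
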