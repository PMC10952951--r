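"subject_id","group","ga_mri","ga_delivery","maternal_age","bmi","ethnicity","parity","liveborn","live_to_discharge","rds","ivh_grade34","bpd","nec","histology_available","chorioamnionitis","funisitis"
"preterm-01","preterm",19.3,20.1,21.5,18.3,"Asian",0,0,0,0,0,0,0,1,1,1
"preterm-02","preterm",19.7,20.5,22.3,18.8,"White",0,0,0,0,0,0,0,1,1,1
"preterm-03","preterm",20.2,21,23.2,19.3,"White",0,0,0,0,0,0,0,1,1,1
"preterm-04","preterm",20.6,21.5,24,19.9,"White",0,0,0,0,0,0,0,1,1,1
"preterm-05","preterm",21,21.9,24.9,20.4,"White",0,0,0,0,0,0,0,1,1,1
"preterm-06","preterm",21.5,22.4,25.7,20.9,"Asian",0,0,0,0,0,0,0,1,1,1
"preterm-07","preterm",21.9,22.8,26.6,21.4,"Other",0,1,0,1,1,1,1,1,1,1
"preterm-08","preterm",22.3,23.2,27.4,21.9,"Mixed",2,1,0,1,0,1,1,1,1,1
"preterm-09","preterm",22.8,23.7,28.3,22.5,"White",0,1,0,1,0,1,1,1,1,1
"preterm-10","preterm",23.2,24.1,29.1,23,"Black",1,1,1,1,0,1,0,1,1,1
"preterm-11","preterm",23.6,24.6,30,23.5,"White",0,1,1,1,0,0,0,1,1,1
"preterm-12","preterm",24.1,25.1,30.8,24,"Black",3,1,1,1,0,0,0,1,1,1
"preterm-13","preterm",24.5,25.5,31.6,24.6,"Asian",0,1,1,1,0,0,0,1,1,1
"preterm-14","preterm",24.9,25.9,32.5,25.1,"Black",0,1,1,1,0,0,0,1,1,1
"preterm-15","preterm",25.4,26.4,33.3,25.6,"White",0,1,1,1,0,0,0,1,1,1
"preterm-16","preterm",25.8,26.9,34.2,26.1,"White",1,1,1,1,0,0,0,1,1,0
"preterm-17","preterm",26.2,27.3,35,26.6,"Asian",0,1,1,1,0,0,0,1,1,0
"preterm-18","preterm",26.7,27.8,35.9,27.2,"Black",1,1,1,1,0,0,0,1,0,0
"preterm-19","preterm",27.1,28.2,36.7,27.7,"White",0,1,1,1,0,0,0,1,0,0
"preterm-20","preterm",27.5,28.6,37.6,28.2,"White",1,1,1,1,0,0,0,1,0,0
"preterm-21","preterm",28,29.1,38.4,28.7,"Mixed",1,1,1,1,0,0,0,1,0,0
"preterm-22","preterm",28.4,29.5,39.3,29.2,"Asian",1,1,1,1,0,0,0,0,0,0
"preterm-23","preterm",28.8,30,40.1,29.8,"White",0,1,1,0,0,0,0,0,0,0
"preterm-24","preterm",29.3,30.3,41,30.3,"White",1,1,1,0,0,0,0,0,0,0
"preterm-25","preterm",29.7,30.3,41.8,30.8,"White",1,1,1,0,0,0,0,0,0,0
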