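"id","group","gender","age_band","web_use","task_time","i01","i02","i03","i04","i05","i06","i07","i08","i09","i10","i11","i12","i13","i14","i15","i16","i17"
"P001","questionnaire","female","18_24","at_least_weekly",82.86,1,1,1,1,1,1,2,1,2,1,1,1,1,1,2,1,1
"P002","diagram","male","25_34","less_than_monthly",92.62,1,1,1,1,2,1,3,4,2,1,3,6,1,1,4,6,2
"P003","questionnaire","male","45_54","at_least_weekly",72.61,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1
"P004","questionnaire","female","over_64","at_least_weekly",84.37,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1,1
"P005","questionnaire","female","under_18","at_least_weekly",83.1,2,2,2,2,2,2,2,2,2,2,2,2,2,1,3,2,2
"P006","diagram","male","35_44","several_times_a_month",87.89,1,1,3,2,2,3,1,1,1,1,1,1,1,1,1,2,1
"P007","diagram","male","45_54","less_than_monthly",100.1,2,1,1,4,2,1,3,4,4,2,1,3,3,1,4,2,2
"P008","diagram","female","35_44","at_least_weekly",84.89,1,1,1,2,1,1,3,1,1,5,1,2,1,1,2,4,1
"P009","questionnaire","female","55_64","at_least_weekly",84.47,2,2,1,2,2,1,1,2,2,2,2,2,1,1,2,2,3
"P010","questionnaire","male","35_44","at_least_weekly",75.75,2,1,1,1,2,1,2,2,1,1,2,2,2,1,2,1,2
"P011","diagram","female","35_44","at_least_weekly",86.75,2,1,5,1,1,1,1,3,3,1,1,1,1,3,2,1,1
"P012","diagram","female","45_54","at_least_weekly",77.66,4,1,2,2,4,4,4,2,4,2,2,3,3,3,3,6,3
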