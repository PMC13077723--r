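variable,category,count
year,2004,32
year,2005,28
year,2006,17
year,2007,13
year,2008,28
year,2009,23
year,2010,17
year,2011,24
year,2012,39
year,2013,35
year,2014,15
year,2015,9
year,2016,26
year,2017,49
sex,Female,242
sex,Male,113
age_band,<18,9
age_band,18-45,89
age_band,45-65,88
age_band,65-75,32
age_band,>=75,42
age_band,Unknown,95
weight_band,<60,27
weight_band,60-80,55
weight_band,>=80,55
weight_band,Unknown,218
reporter,Consumer,106
reporter,Physician,79
reporter,Other health professional,76
reporter,Pharmacist,45
reporter,Unknown,45
reporter,Lawyer,3
reporter,Registered nurse,1
country,United States,120
country,Other,34
route,Other,176
route,Intramuscular,69
route,Intravenous,65
route,Oral,45
outcome,Hospitalization,143
outcome,Other serious,108
outcome,Life threatening,46
outcome,Death,33
outcome,Disability,24
outcome,Required intervention,19
outcome,Congenital anomaly,1
tto_band,<7,144
tto_band,7-28,12
tto_band,28-60,5
tto_band,>=60,5
tto_band,Unknown,31
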