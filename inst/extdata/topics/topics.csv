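name,parent,file
covid,,covid.txt
plandemic,covid,plandemic.txt
hydroxychloroquine,covid,hydroxychloroquine.txt
facemasks,covid,facemasks.txt
covid_mortality,covid,covid_mortality.txt
covid_severity,covid,covid_severity.txt
downplaying_severity,covid_severity,downplaying_severity.txt
vaccines,covid,vaccines.txt
vaccine_hesitancy,vaccines,vaccine_hesitancy.txt
vaccine_misinformation,vaccines,vaccine_misinformation.txt
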