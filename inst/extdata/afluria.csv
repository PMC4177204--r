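vaccine_name,vaccine_vo_id,vae_location,vae_name_insert,vae_name_oae,oae_id,age_category,age_years,vae_occurrence,reference
Afluria,VO_0004001,injection-site,pain,injection-site pain AE,OAE_0000369,child,5-17,60%,Afluria package insert (occurrences synthetic)
Afluria,VO_0004001,injection-site,pain,injection-site pain AE,OAE_0000369,adult,18-64,40%,Afluria package insert (occurrences synthetic)
Afluria,VO_0004001,injection-site,pain,injection-site pain AE,OAE_0000369,senior,65+,20%,Afluria package insert (occurrences synthetic)
Afluria,VO_0004001,systemic,headache,headache AE,OAE_0000377,adult,18-64,25.9%,Afluria package insert (occurrences synthetic)
Afluria,VO_0004001,systemic,malaise,malaise AE,OAE_0000390,adult,18-64,19.1%,Afluria package insert (occurrences synthetic)
Afluria,VO_0004001,systemic,myalgia,myalgia AE,OAE_0000375,adult,18-64,20.5%,Afluria package insert (occurrences synthetic)
Afluria,VO_0004001,systemic,fever,fever AE,OAE_0000361,child,5-17,16%,Afluria package insert (occurrences synthetic)
Afluria,VO_0004001,injection-site,redness,injection-site redness AE,OAE_0001546,child,5-17,21.4%,Afluria package insert (occurrences synthetic)
Afluria,VO_0004001,injection-site,swelling,local swelling AE,OAE_0001139,child,5-17,10.2%,Afluria package insert (occurrences synthetic)
Afluria,VO_0004001,systemic,irritability,irritability AE,OAE_0001105,child,5-17,11.3%,Afluria package insert (occurrences synthetic)
Afluria,VO_0004001,systemic,fatigue,fatigue AE,OAE_0000034,adult,18-64,14.8%,Afluria package insert (occurrences synthetic)
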