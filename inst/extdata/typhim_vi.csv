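vaccine_name,vaccine_vo_id,vae_location,vae_name_insert,vae_name_oae,oae_id,age_category,age_years,vae_occurrence,reference
Typhim Vi,VO_0004101,injection-site,tenderness,injection-site tenderness AE,OAE_0002101,adult,18-40,97.5%,Typhim Vi package insert (other values synthetic)
Typhim Vi,VO_0004101,systemic,headache,headache AE,OAE_0000377,adult,18-40,20.3%,Typhim Vi package insert (other values synthetic)
Typhim Vi,VO_0004101,systemic,fever,fever AE,OAE_0000361,adult,18-40,1.1%,Typhim Vi package insert (other values synthetic)
Comparator vaccine,VO_0004102,injection-site,pain,injection-site pain AE,OAE_0000369,child-adult,2-49,55%,synthetic comparator record
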