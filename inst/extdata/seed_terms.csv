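id,label,parent_ids,source
OAE_0000001,adverse event,,OAE
OAE_0000004,behavior and neurological AE,OAE_0000001,OAE
OAE_0000003,pain AE,OAE_0000004,OAE
OAE_0000369,injection-site pain AE,OAE_0000003,OAE
OAE_0000377,headache AE,OAE_0000003,OAE
OAE_0000375,myalgia AE,OAE_0000003,OAE
OAE_0002101,injection-site tenderness AE,OAE_0000003,OAE
OAE_0001105,irritability AE,OAE_0000004,OAE
OAE_0000390,malaise AE,OAE_0000004,OAE
OAE_0000034,fatigue AE,OAE_0000004,OAE
OAE_0000361,fever AE,OAE_0000001,OAE
OAE_0001139,local swelling AE,OAE_0000001,OAE
OAE_0002001,skin AE,OAE_0000001,OAE
OAE_0002002,redness AE,OAE_0002001,OAE
OAE_0001546,injection-site redness AE,OAE_0002002,OAE
OAE_0000644,injection-site erythema AE,OAE_0002001,OAE
OAE_0000500,injection-site adverse event,OAE_0000001,OAE
OAE_0900001,synthetic AE 01 AE,OAE_0000001,OAE
OAE_0900002,synthetic AE 02 AE,OAE_0000001,OAE
OAE_0900003,synthetic AE 03 AE,OAE_0000001,OAE
OAE_0900004,synthetic AE 04 AE,OAE_0000001,OAE
OAE_0900005,synthetic AE 05 AE,OAE_0000001,OAE
OAE_0900006,synthetic AE 06 AE,OAE_0000001,OAE
OAE_0900007,synthetic AE 07 AE,OAE_0000001,OAE
OAE_0900008,synthetic AE 08 AE,OAE_0000001,OAE
OAE_0900009,synthetic AE 09 AE,OAE_0000001,OAE
OAE_0900010,synthetic AE 10 AE,OAE_0000001,OAE
UBERON_0012100,injection site,,UBERON
VO_0000001,vaccine,,VO
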