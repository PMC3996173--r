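name
ACACIA ST
BANKSIA AVE
CORAL RD
DERWENT CRES
EUCALYPT WAY
FITZGERALD ST
GREVILLEA DR
HIGH ST
IRONBARK CT
JACARANDA AVE
KANGAROO RD
LAKESIDE DR
MULGA ST
NORFOLK AVE
OCEAN PDE
PALM TCE
QUARRY RD
RAILWAY PDE
STATION ST
TELOPEA WAY
UNION ST
VICTORIA AVE
WARATAH ST
WATTLE GROVE
YORK ST
ZAMIA CT
BOTANY RD
CARLTON ST
EDEN CLOSE
FOREST RD
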