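# Calvin-Benson-Bassham route, CO2 -> pyruvate (formate is oxidised for
# energy outside the route; see total_formate_per_pyruvate()).
# Integer stoichiometries over the anionic species of compound_db().
id	equation	label
RBPC	rubp + co2 + h2o = 2 pg3 + 2 h	ribulose-bisphosphate carboxylase (RuBisCO)
PGK	pg3 + atp = bpg13 + adp	phosphoglycerate kinase
GAPDH	bpg13 + nadh + h = g3p + nad + pi	glyceraldehyde-3-phosphate dehydrogenase (NAD+)
TPI	g3p = dhap	triose-phosphate isomerase
FBA	g3p + dhap = fbp	fructose-bisphosphate aldolase
FBP	fbp + h2o = f6p + pi	fructose-1,6-bisphosphatase
TKT1	f6p + g3p = xu5p + e4p	transketolase 1
SBA	e4p + dhap = sbp	sedoheptulose-bisphosphate aldolase
SBP	sbp + h2o = s7p + pi	sedoheptulose-1,7-bisphosphatase
TKT2	s7p + g3p = r5p + xu5p	transketolase 2
RPI	r5p = ru5p	ribose-5-phosphate isomerase
RPE	xu5p = ru5p	ribulose-phosphate epimerase
PRK	ru5p + atp = rubp + adp + h	phosphoribulokinase (Prk)
PGM	pg3 = pg2	phosphoglycerate mutase
ENO	pg2 = pep + h2o	enolase
PYK	pep + adp + h = pyr + atp	pyruvate kinase
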