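# Reductive glycine pathway, formate -> pyruvate.
# Integer stoichiometries over the anionic species of compound_db();
# cofactors, formate, CO2, water and protons are external.
id	equation	label
FTL	for + thf + atp = f10thf + adp + pi	formate--tetrahydrofolate ligase (FtfL)
FCH	f10thf + h = methenylthf + h2o	methenyl-THF cyclohydrolase (FchA)
MTD	methenylthf + nadph = mlthf + nadp	methylene-THF dehydrogenase (MtdA)
GCS	mlthf + co2 + nh4 + nadh = gly + thf + nad	glycine cleavage system, reductive direction (GcvTHP)
SHMT	gly + mlthf + h2o = ser + thf	serine hydroxymethyltransferase (GlyA)
SDA	ser = pyr + nh4	serine deaminase (SdaA)
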