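pathway	reaction	role	metabolite
Glycolysis / TCA cycle	hexokinase	substrate	glucose
Glycolysis / TCA cycle	hexokinase	product	glucose-6-phosphate
Glycolysis / TCA cycle	phosphoglucose_isomerase	substrate	glucose-6-phosphate
Glycolysis / TCA cycle	phosphoglucose_isomerase	product	fructose-6-phosphate
Glycolysis / TCA cycle	phosphofructokinase	substrate	fructose-6-phosphate
Glycolysis / TCA cycle	phosphofructokinase	product	fructose-1,6-bisphosphate
Glycolysis / TCA cycle	lower_glycolysis	substrate	fructose-1,6-bisphosphate
Glycolysis / TCA cycle	lower_glycolysis	product	phosphoenolpyruvate
Glycolysis / TCA cycle	pyruvate_kinase	substrate	phosphoenolpyruvate
Glycolysis / TCA cycle	pyruvate_kinase	product	pyruvate
Glycolysis / TCA cycle	lactate_dehydrogenase	substrate	pyruvate
Glycolysis / TCA cycle	lactate_dehydrogenase	product	lactate
Glycolysis / TCA cycle	pyruvate_dehydrogenase	substrate	pyruvate
Glycolysis / TCA cycle	pyruvate_dehydrogenase	product	acetyl-CoA
Glycolysis / TCA cycle	acetyl-CoA_synthetase	substrate	acetate
Glycolysis / TCA cycle	acetyl-CoA_synthetase	product	acetyl-CoA
Glycolysis / TCA cycle	citrate_synthase	substrate	acetyl-CoA
Glycolysis / TCA cycle	citrate_synthase	substrate	oxaloacetate
Glycolysis / TCA cycle	citrate_synthase	product	citrate
Glycolysis / TCA cycle	isocitrate_dehydrogenase	substrate	citrate
Glycolysis / TCA cycle	isocitrate_dehydrogenase	product	2-oxoglutarate
Glycolysis / TCA cycle	oxoglutarate_dehydrogenase	substrate	2-oxoglutarate
Glycolysis / TCA cycle	oxoglutarate_dehydrogenase	product	succinyl-CoA
Glycolysis / TCA cycle	succinyl-CoA_synthetase	substrate	succinyl-CoA
Glycolysis / TCA cycle	succinyl-CoA_synthetase	product	succinate
Glycolysis / TCA cycle	succinate_dehydrogenase	substrate	succinate
Glycolysis / TCA cycle	succinate_dehydrogenase	product	fumarate
Glycolysis / TCA cycle	fumarase	substrate	fumarate
Glycolysis / TCA cycle	fumarase	product	malate
Glycolysis / TCA cycle	malate_dehydrogenase	substrate	malate
Glycolysis / TCA cycle	malate_dehydrogenase	product	oxaloacetate
Starch and sucrose metabolism	amylase	substrate	glycogen
Starch and sucrose metabolism	amylase	product	maltose
Starch and sucrose metabolism	maltase	substrate	maltose
Starch and sucrose metabolism	maltase	product	glucose
Alanine, aspartate and glutamate metabolism	glutaminase	substrate	glutamine
Alanine, aspartate and glutamate metabolism	glutaminase	product	glutamate
Alanine, aspartate and glutamate metabolism	glutamate_dehydrogenase	substrate	glutamate
Alanine, aspartate and glutamate metabolism	glutamate_dehydrogenase	product	2-oxoglutarate
Alanine, aspartate and glutamate metabolism	alanine_aminotransferase	substrate	alanine
Alanine, aspartate and glutamate metabolism	alanine_aminotransferase	substrate	2-oxoglutarate
Alanine, aspartate and glutamate metabolism	alanine_aminotransferase	product	pyruvate
Alanine, aspartate and glutamate metabolism	alanine_aminotransferase	product	glutamate
Beta-alanine metabolism	aspartate_decarboxylase	substrate	aspartate
Beta-alanine metabolism	aspartate_decarboxylase	product	beta-alanine
Beta-alanine metabolism	histidine_decarboxylase	substrate	histidine
Beta-alanine metabolism	histidine_decarboxylase	product	histamine
Beta-alanine metabolism	carcinine_synthase	substrate	beta-alanine
Beta-alanine metabolism	carcinine_synthase	substrate	histamine
Beta-alanine metabolism	carcinine_synthase	product	carcinine
Tyrosine metabolism	tyrosine_hydroxylase	substrate	tyrosine
Tyrosine metabolism	tyrosine_hydroxylase	product	l-dopa
Tyrosine metabolism	dopa_decarboxylase	substrate	l-dopa
Tyrosine metabolism	dopa_decarboxylase	product	dopamine
Tyrosine metabolism	phenoloxidase	substrate	l-dopa
Tyrosine metabolism	phenoloxidase	product	melanin
Glycerophospholipid metabolism	choline_kinase	substrate	choline
Glycerophospholipid metabolism	choline_kinase	product	phosphocholine
Glycerophospholipid metabolism	phosphocholine_cytidylyltransferase	substrate	phosphocholine
Glycerophospholipid metabolism	phosphocholine_cytidylyltransferase	product	CDP-choline
Glycerophospholipid metabolism	glycerol_kinase	substrate	glycerol
Glycerophospholipid metabolism	glycerol_kinase	product	glycerol-3-phosphate
Lysine degradation	lysine_ketoglutarate_reductase	substrate	lysine
Lysine degradation	lysine_ketoglutarate_reductase	product	saccharopine
Fatty acid biosynthesis	fatty_acid_synthase	substrate	acetyl-CoA
Fatty acid biosynthesis	fatty_acid_synthase	product	palmitate
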