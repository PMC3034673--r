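entry	type	in_vivo
Catalase activity	activity	+
Citrate activity	activity	+
Urease activity	activity	+
Nitrate reduction	activity	+
Acetate	substrate	+
Adonitol	substrate	-
Glycine Betaine	substrate	+
Butyrate	substrate	-
Caprylate	substrate	-
Cellobiose	substrate	-
Choline	substrate	+
Citrate	substrate	+
Creatine	substrate	-
D-fructose	substrate	+
D-galactose	substrate	+
D-glucose	substrate	+
DL-glycerate	substrate	+
DL-alpha-aminobutyrate	substrate	-
D-mannitol	substrate	+
D-mannose	substrate	+
D-melibiose	substrate	-
D-raffinose	substrate	-
D-ribose	substrate	+
D-sorbitol	substrate	+
L-tartrate	substrate	+
D-trehalose	substrate	+
Dulcitol (galactitol)	substrate	+
D-xylose	substrate	+
Erythritol	substrate	+
Ethanol	substrate	+
Fumarate	substrate	+
Galactosamine	substrate	-
Gluconolactone	substrate	-
Glutamate	substrate	+
Glycerol	substrate	+
Glycine	substrate	+
Inulin	substrate	-
Lactate	substrate	-
L-alanine	substrate	-
L-arabinose	substrate	+
L-arginine	substrate	+
L-asparagine	substrate	+
L-fucose	substrate	-
L-glutamine	substrate	+
L-lysine	substrate	+
L-methionine	substrate	-
L-ornithine	substrate	+
L-proline	substrate	+
L-rhamnose	substrate	-
L-serine	substrate	+
L-threonine	substrate	-
L-valine	substrate	-
Malate	substrate	+
Malonate	substrate	+
Maltose	substrate	+
Meso-inositol	substrate	+
Oxalate	substrate	-
Propionate	substrate	+
Putrescine	substrate	-
Sarcosine	substrate	-
Succinate	substrate	+
Sucrose	substrate	+
Tagatose	substrate	+
alpha-lactose	substrate	-
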