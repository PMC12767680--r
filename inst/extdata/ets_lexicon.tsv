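code	name	synonyms	misspellings	pattern_extra	subclasses	lump_group	fate
E400	alginic acid	alginsyre	algininsyre			E40x	non_absorbed
E401	sodium alginate	natriumalginat				E40x	non_absorbed
E402	potassium alginate	kaliumalginat				E40x	non_absorbed
E403	ammonium alginate	ammoniumalginat				E40x	non_absorbed
E404	calcium alginate	kalsiumalginat	calciumalginat			E40x	non_absorbed
E405	propylene glycol alginate	propylenglykolalginat|propan-1,2-diolalginat				self	non_absorbed
E406	agar	agar-agar	agaragar			self	non_absorbed
E407	carrageenan	karragenan|carrageen	karagenan|carragenan	(c|k)ar*age*nan	a	self	non_absorbed
E410	locust bean gum	johannesbrodkjernemel|carob gum	johannesbrodkjernemell			self	non_absorbed
E412	guar gum	guarkjernemel|guargummi	gaur gum			self	non_absorbed
E413	tragacanth	tragant|dragant				self	non_absorbed
E414	gum arabic	acacia gum|gummi arabicum|akasiegummi	gum arabick			self	non_absorbed
E415	xanthan gum	xantangummi|ksantangummi	xantan gum			self	non_absorbed
E416	karaya gum	karayagummi				self	non_absorbed
E417	tara gum	taragummi|tarakjernemel				self	non_absorbed
E418	gellan gum	gellangummi				self	non_absorbed
E420	sorbitol	sorbitolsirup				E42x	absorbed
E421	mannitol	mannit				E42x	absorbed
E422	glycerol	glyserol|glycerin|glyserin				E42x	absorbed
E425	konjac	konjac gum|konjakgummi|glucomannan|glukomannan				self	non_absorbed
E426	soybean hemicellulose	soyahemicellulose				self	non_absorbed
E427	cassia gum	cassiagummi				self	non_absorbed
E431	polyoxyethylene stearate	polyoksyetylenstearat				self	absorbed
E432	polysorbate 20	polysorbat 20				self	absorbed
E433	polysorbate 80	polysorbat 80				self	absorbed
E434	polysorbate 40	polysorbat 40				self	absorbed
E435	polysorbate 60	polysorbat 60				self	absorbed
E436	polysorbate 65	polysorbat 65				self	absorbed
E440	pectin	pektin|pectins|pektiner	pectine			self	non_absorbed
E442	ammonium phosphatides	ammoniumfosfatider				self	absorbed
E445	ester gum	treharpiksestere|glyserolestere av treharpiks				self	absorbed
E450	diphosphates	difosfat|difosfater|diphosphate	diphosfat			E45x	absorbed
E451	triphosphates	trifosfat|trifosfater|triphosphate	triphosfat			E45x	absorbed
E452	polyphosphates	polyfosfat|polyfosfater|polyphosphate				E45x	absorbed
E456	potassium polyaspartate	kaliumpolyaspartat				self	absorbed
E459	beta-cyclodextrin	betacyklodekstrin|beta-syklodekstrin				self	absorbed
E460	microcrystalline cellulose	mikrokrystallinsk cellulose|cellulosepulver|powdered cellulose	mikrokristallinsk cellulose			self	non_absorbed
E461	methylcellulose	metylcellulose	methylcelulose			self	non_absorbed
E463	hydroxypropylcellulose	hydroksypropylcellulose				self	non_absorbed
E464	hypromellose	hydroksypropylmetylcellulose|hpmc				self	non_absorbed
E465	ethylmethylcellulose	etylmetylcellulose|metyletylcellulose				self	non_absorbed
E466	carboxymethylcellulose	karboksymetylcellulose|cellulose gum|cmc	carboxymetylcellulose			self	non_absorbed
E470	salts of fatty acids	fettsyresalter|magnesiumsalter av fettsyrer			ab	E47x	absorbed
E471	mono- and diglycerides of fatty acids	mono- og diglyserider av fettsyrer|monodiglyserider	mono og diglyserider av fettsyrer			E47x	absorbed
E472	esters of mono- and diglycerides	estere av mono- og diglyserider|acetem|lactem|citrem|datem			abcdef	E47x	absorbed
E473	sucrose esters of fatty acids	sukroseestere av fettsyrer|sucrose esters				E47x	absorbed
E474	sucroglycerides	sukroglyserider				E47x	absorbed
E475	polyglycerol esters of fatty acids	polyglyserolestere av fettsyrer|polyglycerol esters				E47x	absorbed
E476	polyglycerol polyricinoleate	polyglyserolpolyrisinoleat|pgpr				E47x	absorbed
E477	propylene glycol esters of fatty acids	propylenglykolestere av fettsyrer				E47x	absorbed
E479	thermally oxidized soybean oil	termisk oksidert soyaolje			b	self	absorbed
E481	sodium stearoyl-2-lactylate	natriumstearoyllaktylat|sodium stearoyl lactylate				self	absorbed
E482	calcium stearoyl-2-lactylate	kalsiumstearoyllaktylat|calcium stearoyl lactylate				self	absorbed
E483	stearyl tartrate	stearyltartrat				self	absorbed
E491	sorbitan monostearate	sorbitanmonostearat				self	absorbed
E493	sorbitan monolaurate	sorbitanmonolaurat				self	absorbed
E494	sorbitan monooleate	sorbitanmonooleat				self	absorbed
E495	sorbitan monopalmitate	sorbitanmonopalmitat				self	absorbed
E499	stigmasterol-rich plant sterols	stigmasterol				self	absorbed
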