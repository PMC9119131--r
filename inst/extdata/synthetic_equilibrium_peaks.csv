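condition_id,covariate,peak_id,conformer,volume,volume_sd,unperturbed
T278,278,p1.WT,WT,0.447805317457879,,TRUE
T278,278,p2.WT,WT,0.422547530832354,,TRUE
T278,278,p3.WT,WT,0.43447155529349,,TRUE
T278,278,p4.WT,WT,0.43800077648645,,TRUE
T278,278,p5.WT,WT,0.435007989236099,,TRUE
T278,278,p1.SLIP,SLIP,0.567974323348297,,TRUE
T278,278,p2.SLIP,SLIP,0.596211037370602,,TRUE
T278,278,p3.SLIP,SLIP,0.568169675908522,,TRUE
T278,278,p4.SLIP,SLIP,0.605344868081321,,TRUE
T278,278,p5.SLIP,SLIP,0.568714318708391,,TRUE
T283,283,p1.WT,WT,0.50295528199181,,TRUE
T283,283,p2.WT,WT,0.517985843089874,,TRUE
T283,283,p3.WT,WT,0.463917867429539,,TRUE
T283,283,p4.WT,WT,0.479623871364481,,TRUE
T283,283,p5.WT,WT,0.481721061950794,,TRUE
T283,283,p1.SLIP,SLIP,0.525833929584906,,TRUE
T283,283,p2.SLIP,SLIP,0.511519418460459,,TRUE
T283,283,p3.SLIP,SLIP,0.47638934806539,,TRUE
T283,283,p4.SLIP,SLIP,0.479485510323952,,TRUE
T283,283,p5.SLIP,SLIP,0.536735655808247,,TRUE
T288,288,p1.WT,WT,0.531131205290518,,TRUE
T288,288,p2.WT,WT,0.508151146414904,,TRUE
T288,288,p3.WT,WT,0.53328170400693,,TRUE
T288,288,p4.WT,WT,0.555927681529018,,TRUE
T288,288,p5.WT,WT,0.567391299454558,,TRUE
T288,288,p1.SLIP,SLIP,0.457565694276483,,TRUE
T288,288,p2.SLIP,SLIP,0.459948852181089,,TRUE
T288,288,p3.SLIP,SLIP,0.439636672354126,,TRUE
T288,288,p4.SLIP,SLIP,0.469952419584064,,TRUE
T288,288,p5.SLIP,SLIP,0.454699203776452,,TRUE
T293,293,p1.WT,WT,0.593959436223709,,TRUE
T293,293,p2.WT,WT,0.598418870878027,,TRUE
T293,293,p3.WT,WT,0.604376119814406,,TRUE
T293,293,p4.WT,WT,0.575297278870504,,TRUE
T293,293,p5.WT,WT,0.594842011770383,,TRUE
T293,293,p1.SLIP,SLIP,0.392886269935406,,TRUE
T293,293,p2.SLIP,SLIP,0.404030503566381,,TRUE
T293,293,p3.SLIP,SLIP,0.403226068918767,,TRUE
T293,293,p4.SLIP,SLIP,0.384755826107805,,TRUE
T293,293,p5.SLIP,SLIP,0.414097846961957,,TRUE
T298,298,p1.WT,WT,0.636397536038193,,TRUE
T298,298,p2.WT,WT,0.625665306230438,,TRUE
T298,298,p3.WT,WT,0.64702480904755,,TRUE
T298,298,p4.WT,WT,0.618841149031642,,TRUE
T298,298,p5.WT,WT,0.607046659181878,,TRUE
T298,298,p1.SLIP,SLIP,0.371868933341542,,TRUE
T298,298,p2.SLIP,SLIP,0.358247296665275,,TRUE
T298,298,p3.SLIP,SLIP,0.383321145065456,,TRUE
T298,298,p4.SLIP,SLIP,0.362353178183741,,TRUE
T298,298,p5.SLIP,SLIP,0.374362603132925,,TRUE
T303,303,p1.WT,WT,0.681836493999881,,TRUE
T303,303,p2.WT,WT,0.659593949936336,,TRUE
T303,303,p3.WT,WT,0.707965591422918,,TRUE
T303,303,p4.WT,WT,0.688432269912944,,TRUE
T303,303,p5.WT,WT,0.677105105034871,,TRUE
T303,303,p1.SLIP,SLIP,0.326966516716547,,TRUE
T303,303,p2.SLIP,SLIP,0.330940034793033,,TRUE
T303,303,p3.SLIP,SLIP,0.325140531733192,,TRUE
T303,303,p4.SLIP,SLIP,0.296423923788823,,TRUE
T303,303,p5.SLIP,SLIP,0.327048239120841,,TRUE
T308,308,p1.WT,WT,0.667887493572647,,TRUE
T308,308,p2.WT,WT,0.679046742544744,,TRUE
T308,308,p3.WT,WT,0.687172315995593,,TRUE
T308,308,p4.WT,WT,0.704238417052198,,TRUE
T308,308,p5.WT,WT,0.660713586921254,,TRUE
T308,308,p1.SLIP,SLIP,0.337184616826967,,TRUE
T308,308,p2.SLIP,SLIP,0.327548550996006,,TRUE
T308,308,p3.SLIP,SLIP,0.33452489126285,,TRUE
T308,308,p4.SLIP,SLIP,0.33334525638869,,TRUE
T308,308,p5.SLIP,SLIP,0.331353106910037,,TRUE
T313,313,p1.WT,WT,0.654484411519315,,TRUE
T313,313,p2.WT,WT,0.673460479657837,,TRUE
T313,313,p3.WT,WT,0.688032198081607,,TRUE
T313,313,p4.WT,WT,0.656245548487899,,TRUE
T313,313,p5.WT,WT,0.664379216793861,,TRUE
T313,313,p1.SLIP,SLIP,0.329965825100525,,TRUE
T313,313,p2.SLIP,SLIP,0.331823530557428,,TRUE
T313,313,p3.SLIP,SLIP,0.328807677322928,,TRUE
T313,313,p4.SLIP,SLIP,0.315764221575764,,TRUE
T313,313,p5.SLIP,SLIP,0.313743918385555,,TRUE
T318,318,p1.WT,WT,0.7066286657777,,TRUE
T318,318,p2.WT,WT,0.680528839606018,,TRUE
T318,318,p3.WT,WT,0.677078289756157,,TRUE
T318,318,p4.WT,WT,0.672840442605652,,TRUE
T318,318,p5.WT,WT,0.651522863220423,,TRUE
T318,318,p1.SLIP,SLIP,0.330272770945857,,TRUE
T318,318,p2.SLIP,SLIP,0.32216066582353,,TRUE
T318,318,p3.SLIP,SLIP,0.322493069311642,,TRUE
T318,318,p4.SLIP,SLIP,0.333471434001925,,TRUE
T318,318,p5.SLIP,SLIP,0.332357355732441,,TRUE
T323,323,p1.WT,WT,0.704077473214676,,TRUE
T323,323,p2.WT,WT,0.665708770337272,,TRUE
T323,323,p3.WT,WT,0.688586101724263,,TRUE
T323,323,p4.WT,WT,0.704056230954722,,TRUE
T323,323,p5.WT,WT,0.653157389825669,,TRUE
T323,323,p1.SLIP,SLIP,0.316000925883713,,TRUE
T323,323,p2.SLIP,SLIP,0.313443333318585,,TRUE
T323,323,p3.SLIP,SLIP,0.310379747148634,,TRUE
T323,323,p4.SLIP,SLIP,0.32504448525145,,TRUE
T323,323,p5.SLIP,SLIP,0.330681222362675,,TRUE
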