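condition_id,covariate,peak_id,conformer,volume,volume_sd,unperturbed
L0,0,p1.WT,WT,104.150804521567,,TRUE
L0,0,p2.WT,WT,98.2763347577507,,TRUE
L0,0,p3.WT,WT,101.049630858414,,TRUE
L0,0,p4.WT,WT,101.870459044796,,TRUE
L0,0,p5.WT,WT,101.174394956823,,TRUE
L0,0,p1.SLIP,SLIP,99.6373773584056,,TRUE
L0,0,p2.SLIP,SLIP,104.59082686263,,TRUE
L0,0,p3.SLIP,SLIP,99.6716472469567,,TRUE
L0,0,p4.SLIP,SLIP,106.193136861235,,TRUE
L0,0,p5.SLIP,SLIP,99.767191672022,,TRUE
L25,25,p1.WT,WT,105.579056826326,,TRUE
L25,25,p2.WT,WT,108.73423288496,,TRUE
L25,25,p3.WT,WT,97.3844249017926,,TRUE
L25,25,p4.WT,WT,100.681388153465,,TRUE
L25,25,p5.WT,WT,101.1216249141,,TRUE
L25,25,p1.SLIP,SLIP,100.277862843126,,TRUE
L25,25,p2.SLIP,SLIP,97.5480492985021,,TRUE
L25,25,p3.SLIP,SLIP,90.8486558540223,,TRUE
L25,25,p4.SLIP,SLIP,91.439101842453,,TRUE
L25,25,p5.SLIP,SLIP,102.356849659059,,TRUE
L50,50,p1.WT,WT,102.112297566603,,TRUE
L50,50,p2.WT,WT,97.6942807251314,,TRUE
L50,50,p3.WT,WT,102.52574035185,,TRUE
L50,50,p4.WT,WT,106.879528591721,,TRUE
L50,50,p5.WT,WT,109.08345928369,,TRUE
L50,50,p1.SLIP,SLIP,95.6118311683543,,TRUE
L50,50,p2.SLIP,SLIP,96.1098101341574,,TRUE
L50,50,p3.SLIP,SLIP,91.8654257046216,,TRUE
L50,50,p4.SLIP,SLIP,98.2001316105672,,TRUE
L50,50,p5.SLIP,SLIP,95.0128561814554,,TRUE
L100,100,p1.WT,WT,107.449066601574,,TRUE
L100,100,p2.WT,WT,108.255791879353,,TRUE
L100,100,p3.WT,WT,109.33347631147,,TRUE
L100,100,p4.WT,WT,104.073025636348,,TRUE
L100,100,p5.WT,WT,107.60872719944,,TRUE
L100,100,p1.SLIP,SLIP,89.2045511415855,,TRUE
L100,100,p2.SLIP,SLIP,91.734841546062,,TRUE
L100,100,p3.SLIP,SLIP,91.5521952253469,,TRUE
L100,100,p4.SLIP,SLIP,87.3585395913671,,TRUE
L100,100,p5.SLIP,SLIP,94.0206247803253,,TRUE
L200,200,p1.WT,WT,112.101169050522,,TRUE
L200,200,p2.WT,WT,110.210691102638,,TRUE
L200,200,p3.WT,WT,113.973158900741,,TRUE
L200,200,p4.WT,WT,109.008618567078,,TRUE
L200,200,p5.WT,WT,106.931023941643,,TRUE
L200,200,p1.SLIP,SLIP,89.655735892708,,TRUE
L200,200,p2.SLIP,SLIP,86.3716275664225,,TRUE
L200,200,p3.SLIP,SLIP,92.4168067368905,,TRUE
L200,200,p4.SLIP,SLIP,87.361535020424,,TRUE
L200,200,p5.SLIP,SLIP,90.2569471802733,,TRUE
L500,500,p1.WT,WT,125.925316863149,,TRUE
L500,500,p2.WT,WT,121.817441391988,,TRUE
L500,500,p3.WT,WT,130.750982402173,,TRUE
L500,500,p4.WT,WT,127.143461065051,,TRUE
L500,500,p5.WT,WT,125.051497905284,,TRUE
L500,500,p1.SLIP,SLIP,75.8210841453971,,TRUE
L500,500,p2.SLIP,SLIP,76.7425132001395,,TRUE
L500,500,p3.SLIP,SLIP,75.3976519161232,,TRUE
L500,500,p4.SLIP,SLIP,68.7384858058272,,TRUE
L500,500,p5.SLIP,SLIP,75.8400349583268,,TRUE
L1000,1000,p1.WT,WT,138.601250831112,,TRUE
L1000,1000,p2.WT,WT,140.917038865403,,TRUE
L1000,1000,p3.WT,WT,142.603272931539,,TRUE
L1000,1000,p4.WT,WT,146.14486186084,,TRUE
L1000,1000,p5.WT,WT,137.11250842345,,TRUE
L1000,1000,p1.SLIP,SLIP,62.1551646048828,,TRUE
L1000,1000,p2.SLIP,SLIP,60.3788936008761,,TRUE
L1000,1000,p3.SLIP,SLIP,61.6648822136005,,TRUE
L1000,1000,p4.SLIP,SLIP,61.4474333855162,,TRUE
L1000,1000,p5.SLIP,SLIP,61.080209103672,,TRUE
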