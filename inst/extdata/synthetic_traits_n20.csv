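species,order,family,genus,environment,predator_mass,prey_min,prey_max,log_mass,log_prey_min,log_prey_max,log_prey_range
Gen1_sp1,Ord1,Fam1,Gen1,terrestrial, 29.59478274516044,3.4422180566722962,30.524315619248021,1.4712151561705415,0.53683837842905358,1.4846459354796204,1.4326822982912952
Gen2_sp1,Ord1,Fam1,Gen2,terrestrial,23.819655026202945,1.6808257880749755,6.3943753134557246,1.3769354674195815,0.22552270261347518,0.80579812329932665,0.67334807458421353
Gen2_sp2,Ord1,Fam1,Gen2,terrestrial,0.42410269934543299,0.0094153950430489151,0.022014468210788632,-0.37252896331700458,-2.0261614535106176,-1.6572918010474944,-1.8996614019412668
Gen3_sp1,Ord2,Fam2,Gen3,terrestrial,0.38636041198628934,0.00014459527547514302,0.00026103215087866104,-0.41300737950472732,-3.8398458970041132,-3.5833059980668556,-3.9339094574175077
Gen4_sp1,Ord3,Fam3,Gen4,terrestrial,0.0031939793219661213,5.1768488163672466e-06,5.8085199070953241e-06,-2.4956678998397024,-5.2859345178800687,-5.2359345178800689,-6.1995089987183736
Gen4_sp2,Ord3,Fam3,Gen4,terrestrial,79.564048419688788,0.31188167031618497,2.1997131982474754,1.9007168730144834,-0.50601014853383131,0.34236606057761954,0.27596323479551121
Gen5_sp1,Ord3,Fam3,Gen5,terrestrial,149.24551149966138,4.7180760062931704,25.537142535687973,2.1739012787612628, 0.673764932914102,1.4071723005072792,1.3184612530217188
Gen5_sp2,Ord3,Fam3,Gen5,terrestrial,5.1674682464755159,0.1589899083371285,0.65148755251852042,0.7132778166156617,-0.79863044104174952,-0.18609387760935939,-0.30759584257036715
Gen5_sp3,Ord3,Fam3,Gen5,terrestrial,1580.9356165964052,18.465796035229996,257.76039725135735,  3.19891418370434,1.2663680342321131, 2.411216192395206,2.3789329005002156
Gen5_sp4,Ord3,Fam3,Gen5,terrestrial,14.018723936907078,0.1287962010746847,0.80187695913367552,1.1467084835035595,-0.89009694657739513,-0.095892265217981207,-0.17193282481726971
Gen5_sp5,Ord3,Fam3,Gen5,terrestrial,0.85821573357195158,0.0012459495154939265,0.0034541598934054816,-0.066403527858760039,-2.9044995544558176,-2.4616575627684276,-2.6559595534003968
Gen6_sp1,Ord4,Fam4,Gen6,aquatic,136.95376533623613,0.00017214936121377186,0.0016096497717897555,2.1365739770227665,-3.764094584471644,-2.7932686076483622,-2.8423920225959955
Gen6_sp2,Ord4,Fam4,Gen6,aquatic,312.94369021941077,0.0025473895317379013,0.012941221676183154,2.4954661994409442,-2.5939046402153068,-1.8880247234987755,-1.9832243011104096
Gen7_sp1,Ord4,Fam4,Gen7,aquatic,3.4317853846313779,0.11561833734887503,0.57858517008265253,0.53552012032331464,-0.93697328029389793,-0.23763270209800891,-0.33445012102666272
Gen8_sp1,Ord4,Fam4,Gen8,aquatic,7.0133370092633678,0.0063779188001736199,0.028923843228296633,0.8459247083907051,-2.1953210142340147,-1.5387440010750364,-1.6469319530474968
Gen8_sp2,Ord4,Fam4,Gen8,aquatic,1778.5001080505256,0.005824856158323081,0.060687585662476992,3.2500538959068122,-2.2347147948372008,-1.2169001397268726,-1.2607225893836229
Gen8_sp3,Ord4,Fam4,Gen8,aquatic,1348.9468757570739,0.0026287175207972027,0.022015646750837097, 3.129994846617898,-2.5802560802117345,-1.6572685518036385,-1.7124909750400032
Gen8_sp4,Ord4,Fam4,Gen8,aquatic,0.0015905387103366598,0.0062950044918174955,0.0070631112097329805,-2.7984557566219923,-2.2010039556640049,-2.151003955664005,-3.1145784365023088
Gen9_sp1,Ord4,Fam4,Gen9,aquatic,0.013765161546738599,0.0015277817217422328,0.001832937974819821,-1.8612186873984786,-2.8159386901415453,-2.7368522309730001,-3.5154777263160484
Gen9_sp2,Ord4,Fam4,Gen9,aquatic, 11.82712995313196,0.0063747224079342508,0.040747565485260449,1.0728793687411531,-2.1955387221610194,-1.3898983336209769,-1.4637845446236468
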