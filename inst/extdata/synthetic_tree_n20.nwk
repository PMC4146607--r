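((((Gen6_sp1:0.03970021834,Gen6_sp2:0.03970021834):0.2511548008,Gen7_sp1:0.2908550192):0.01586915389,(((Gen8_sp1:0.06018956533,(Gen8_sp2:0.001418309772,Gen8_sp3:0.001418309772):0.05877125556):0.0002064376189,Gen8_sp4:0.06039600295):0.2457137844,Gen9_sp1:0.3061097873,Gen9_sp2:0.3061097873):0.0006143857632):0.6932758269,((Gen4_sp1:0.06335818445,Gen4_sp2:0.06335818445):0.3895923273,((Gen5_sp1:0.01849285059,Gen5_sp2:0.01849285059):0.1275303548,(Gen5_sp3:0.07757577424,(Gen5_sp4:0.03418679179,Gen5_sp5:0.03418679179):0.04338898245):0.06844743118):0.3069273063):0.5470494883,Gen3_sp1:1,(Gen2_sp1:0.2638007182,Gen1_sp1:0.2638007182,Gen2_sp2:0.2638007182):0.7361992818);
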