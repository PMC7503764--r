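mass,sequence,protein,source
836.4512,LSSPATLNSR,TG_SYNTH,WDTC
904.4682,FSPDDSAGASALLR,TG_SYNTH,WDTC
1105.5832,VLDELTGLGSSK,HSPA5_SYNTH,ATC
1183.6301,SPQELGHLMSR,HNRNPUL2_SYNTH,ATC
1184.6417,TLDGAAHLGEVR,HNRNPUL2_SYNTH,WDTC
1296.6851,GLSDGEWQLVLNVWGK,CALCA_SYNTH,MTC
1478.7293,EDLHWPAALTVEK,CHGA_SYNTH,MTC
1570.6774,SELEEQLTPVAEETR,APOE_SYNTH,MTC
1638.8132,VNHVTLSQPKIVK,TTR_SYNTH,MTC
1790.8921,DGLDAASYYAPVREK,VIM_SYNTH,ATC
2045.0231,TVQAVLTVPGQENAVSLGQK,CEACAM5_SYNTH,MTC
2211.1040,ILGGHLDAKGSFPWQAKMVS,KRT8_SYNTH,ATC
2465.1988,QLEDGSPRTGQIFKQTYSKFDTN,ENO1_SYNTH,ATC
2705.2719,AVMDDFAAFVEKCCKADDKETCFAE,ALB_SYNTH,WDTC
3093.5122,GITWGEETLMEYLENPKKYIPGTKMIFA,LDHA_SYNTH,WDTC
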