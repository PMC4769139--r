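>lrr_exemplar_1 family=LRR provenance=synthetic plant LRR consensus repeat x8
LTELDLSNNQLSGKIPAELGNLKNLTELDLSNNQLSGKIPAELGNLKNLTELDLSNNQLSGKIPAELGNLKNLTELDLSNNQLSGKIPAELGNLKNLTELDLSNNQLSGKIPAELGNLKNLTELDLSNNQLSGKIPAELGNLKNLTELDLSNNQLSGKIPAELGNLKNLTELDLSNNQLSGKIPAELGNLKN
>kinase_exemplar_1 family=KINASE provenance=synthetic Ser/Thr protein kinase catalytic domain
MELLGKGSFGSVFKAELRNGHAVFMVNRITADTSTMGSMCAIKFAWMLIEFSNTNEDLNLGFRAVKVLNLEESLHSHFRHREESPLTDAVIDCPKQGVNDGLAGIGHKNLVKLLGFCDEGDERLLVFELMPNGSLDNHLFGTLEILKAEDPKGLLVDLGMFTEITRRGGEMKLDWNTRLKIAIGAAKGLAFLHEEAEHTTKLRNTSKKLERNESKRTEFHGTIIHRDVKASNVLLDENLNAKVSDFGLAKLLFRRMQKNAPRALSPTNAMVAGTHGHVAPEWALNTVPEDPGLADMKRGKASVAG
>fh2_exemplar_1 family=FH2 provenance=synthetic formin homology 2 domain
MDSLLEQIRKGVQLKKVETSSISANRPPFQVVTTFPAVGPAALLKATTETNALNVLFGQMMNQIQSASHIGVKDELSNKEKFIAKHVNVGLGEAVLWKGGVRWDKLDAARNGNLDLSKLSALFAQNLQKSLKLGKIAAIMEGVKLPAKKRTAVMIQIMELDSDLLDVEHVENLARFLPTDEEQAQGFFAPSAQEVSIEILGCVAILELQTVEELGECEQFFLELMKVPRFEARLRVFLPRALISLVQMEAVVACILGMVDFW
>other_exemplar_1 family=OTHER provenance=synthetic globular non-HRGP domain
MHWENSEAVKMENTTFLASDIKVNVSLPELLHENFSKLATIDHIIKDVCRKRFEVLVPATHGALNKIEVRNLHALQIDGTIHFKLWHKDRFLIRSQACVLEAKGTAAVPSLAICNKLIEDIIKSLMLSGAIDFEQVSANDLSEDDSVGDFNELNLARVGEQELFHISRFAPNEWRQ
>classical_ext_exemplar_1 family=CLASSICAL_EXT provenance=synthetic classical EXT SP4/YXY repeat region
SPPPPYVYKHWESPPPTYKYKWSPPPPYVYKHWESPPPTYKYKWSPPPPYVYKHWESPPPTYKYKWSPPPPYVYKHWESPPPTYKYKWSPPPPYVYKHWESPPPTYKYKWSPPPPYVYKHWESPPPTYKYKWSPPPPYVYKHWESPPPTYKYKW
>short_ext_exemplar_1 family=SHORT_EXT provenance=synthetic short EXT repeat region
SPPPTYVYHWKSPPPPYKYEWSPPPTYVYHWKSPPPPYKYEWSPPPTYVYHWKSPPPPYKYEW
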