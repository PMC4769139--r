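>Bradi3g10280_synthetic_standin constructed to the reported motif counts: 11 SP3, 3 SP4, 19 QAAA
MTVSPPPTGVSPPPTGVSPPPTGVSPPPTGVSPPPTGVSPPPTGVSPPPTGVSPPPTGVSPPPTGVSPPPTGVSPPPTGVSPPPPTGVSPPPPTGVSPPPPTGVQAAAQAAAQAAAQAAAQAAAQAAAQAAAQAAAQAAAQAAAQAAAQAAAQAAAQAAAQAAAQAAAQAAAQAAAQAAATVG
>MA_74039g0010_synthetic_standin constructed to the reported motif counts: 35 SP(3-5) runs, no signal peptide
MDETVSPPPTVSPPPTVSPPPTVSPPPTVSPPPPTVSPPPPTVSPPPPPTVSPPPTVSPPPTVSPPPTVSPPPTVSPPPPTVSPPPPTVSPPPPPTVSPPPTVSPPPTVSPPPTVSPPPTVSPPPPTVSPPPPTVSPPPPPTVSPPPTVSPPPTVSPPPTVSPPPTVSPPPPTVSPPPPTVSPPPPPTVSPPPTVSPPPTVSPPPTVSPPPTVSPPPPTVSPPPPTVSPPPPPTVGTE
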