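id,name,smiles,formula,dili_class,atc_codes,year,peptide_flag,nucleic_acid_flag
D001,acetaminophen,CC(=O)Nc1ccc(O)cc1,,Most,N,2010,FALSE,FALSE
D002,aspirin,CC(=O)Oc1ccccc1C(=O)O,,Less,A;N,2011,FALSE,FALSE
D003,ibuprofen,CC(C)Cc1ccc(cc1)C(C)C(=O)O,,Less,M,2012,FALSE,FALSE
D004,caffeine,Cn1cnc2c1c(=O)n(C)c(=O)n2C,,No,N,2013,FALSE,FALSE
D005,fluorouracil,Fc1c[nH]c(=O)[nH]c1=O,,Most,L,2014,FALSE,FALSE
D006,sertraline hydrochloride,CNC1CCC(c2ccc(Cl)c(Cl)c2)c2ccccc21.Cl,,Most,N,2015,FALSE,FALSE
D007,sodium valproate,CCCC(CCC)C(=O)[O-].[Na+],,Most,N,2016,FALSE,FALSE
D008,cisplatin-like,N.N.Cl[Pt]Cl,,No,L,2017,FALSE,FALSE
D009,peptide-drug,,C257H383N65O77S6,No,H,2018,TRUE,FALSE
D010,halothane,FC(F)(F)C(Cl)Br,,No,N,2019,FALSE,FALSE
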