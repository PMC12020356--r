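"id","name","abbreviation","cas","formula","mw_neutral","log_kow","solubility","pka1","pka2","species_charges","subfamily","n_fluorinated_carbons","provisional"
"tfa","Trifluoroacetic acid","TFA","76-05-1","C2HF3O2",114.02,0.5,1e+06,0.3,,"0;-1","PFCA",1,FALSE
"pfba","Perfluorobutanoic acid","PFBA","375-22-4","C4HF7O2",214.04,2.1,2e+05,0.5,,"0;-1","PFCA",3,FALSE
"pfpea","Perfluoropentanoic acid","PFPeA","2706-90-3","C5HF9O2",264.04,2.8,1e+05,0.5,,"0;-1","PFCA",4,FALSE
"pfhxa","Perfluorohexanoic acid","PFHxA","307-24-4","C6HF11O2",314.05,3.5,30000,0.5,,"0;-1","PFCA",5,FALSE
"pfhpa","Perfluoroheptanoic acid","PFHpA","375-85-9","C7HF13O2",364.06,4.2,12000,0.5,,"0;-1","PFCA",6,FALSE
"pfoa","Perfluorooctanoic acid","PFOA","335-67-1","C8HF15O2",414.06,4.8,3400,0.5,,"0;-1","PFCA",7,FALSE
"pfna","Perfluorononanoic acid","PFNA","375-95-1","C9HF17O2",464.07,5.5,1600,0.5,,"0;-1","PFCA",8,FALSE
"pfda","Perfluorodecanoic acid","PFDA","335-76-2","C10HF19O2",514.08,6.1,500,0.5,,"0;-1","PFCA",9,FALSE
"pfuna","Perfluoroundecanoic acid","PFUnA","2058-94-8","C11HF21O2",564.08,6.8,150,0.5,,"0;-1","PFCA",10,FALSE
"pfdoa","Perfluorododecanoic acid","PFDoA","307-55-1","C12HF23O2",614.09,7.4,40,0.5,,"0;-1","PFCA",11,FALSE
"pftra","Perfluorotridecanoic acid","PFTrA","72629-94-8","C13HF25O2",664.1,8.1,12,0.5,,"0;-1","PFCA",12,FALSE
"pftea","Perfluorotetradecanoic acid","PFTeA","376-06-7","C14HF27O2",714.11,8.7,4,0.5,,"0;-1","PFCA",13,FALSE
"pfbs","Perfluorobutane sulfonic acid","PFBS","375-73-5","C4HF9O3S",300.09,2.6,52000,-3.3,,"0;-1","PFSA",4,FALSE
"pfpes","Perfluoropentane sulfonic acid","PFPeS","2706-91-4","C5HF11O3S",350.1,3.3,20000,-3.3,,"0;-1","PFSA",5,FALSE
"pfhxs","Perfluorohexane sulfonic acid","PFHxS","355-46-4","C6HF13O3S",400.1,3.9,6000,-3.3,,"0;-1","PFSA",6,FALSE
"pfhps","Perfluoroheptane sulfonic acid","PFHpS","375-92-8","C7HF15O3S",450.11,4.6,2000,-3.3,,"0;-1","PFSA",7,FALSE
"pfos","Perfluorooctane sulfonic acid","PFOS","1763-23-1","C8HF17O3S",500.12,5.2,570,-3.3,,"0;-1","PFSA",8,FALSE
"pfns","Perfluorononane sulfonic acid","PFNS","68259-12-1","C9HF19O3S",550.13,5.9,200,-3.3,,"0;-1","PFSA",9,FALSE
"pfds","Perfluorodecane sulfonic acid","PFDS","335-77-3","C10HF21O3S",600.13,6.5,70,-3.3,,"0;-1","PFSA",10,FALSE
"pfetchxs","Perfluoroethylcyclohexane sulfonic acid","PFEtCHxS","646-83-3","C8HF15O3S",462.12,4.9,1000,-3.3,,"0;-1","PFSA",8,TRUE
"pfhxpa","Perfluorohexyl phosphonic acid","PFHxPA","40143-76-8","C6H2F13O3P",400.03,3.2,5000,0.8,6.2,"0;-1;-2","PFPA",6,TRUE
"pfopa","Perfluorooctyl phosphonic acid","PFOPA","40143-78-0","C8H2F17O3P",500.04,4.6,1500,0.8,6.2,"0;-1;-2","PFPA",8,TRUE
"pfdpa","Perfluorodecyl phosphonic acid","PFDPA","52299-26-0","C10H2F21O3P",600.06,6,400,0.8,6.2,"0;-1;-2","PFPA",10,TRUE
"pfpia_6_6","Bis(perfluorohexyl) phosphinic acid","C6/6 PFPiA","40143-77-9","C12HF26O2P",702.06,7,10,0.5,,"0;-1","PFPiA",12,TRUE
"pfpia_6_8","Perfluorohexyl-perfluorooctyl phosphinic acid","C6/8 PFPiA","610800-34-5","C14HF30O2P",802.07,8,3,0.5,,"0;-1","PFPiA",14,TRUE
"pfpia_8_8","Bis(perfluorooctyl) phosphinic acid","C8/8 PFPiA","40143-79-1","C16HF34O2P",902.09,9,1,0.5,,"0;-1","PFPiA",16,TRUE
"fbsa","Perfluorobutane sulfonamide","FBSA","30334-69-1","C4H2F9NO2S",299.11,2.5,3000,6.2,,"0;-1","FOSA",4,TRUE
"fhxsa","Perfluorohexane sulfonamide","FHxSA","41997-13-1","C6H2F13NO2S",399.12,3.9,600,6.2,,"0;-1","FOSA",6,TRUE
"pfosa","Perfluorooctane sulfonamide","PFOSA","754-91-6","C8H2F17NO2S",499.14,5.3,120,6.2,,"0;-1","FOSA",8,FALSE
"etfosa","N-Ethyl perfluorooctane sulfonamide","Et-FOSA","4151-50-2","C10H6F17NO2S",527.19,6,20,6.8,,"0;-1","FOSA",8,TRUE
"mefosaa","N-Methyl perfluorooctane sulfonamidoacetic acid","N-MeFOSAA","2355-31-9","C11H6F17NO4S",571.2,5.1,200,3.7,,"0;-1","FOSAA",8,TRUE
"etfosaa","N-Ethyl perfluorooctane sulfonamidoacetic acid","N-EtFOSAA","2991-50-6","C12H8F17NO4S",585.22,5.6,150,3.7,,"0;-1","FOSAA",8,TRUE
"genx","Hexafluoropropylene oxide dimer acid","GenX","13252-13-6","C6HF11O3",330.05,3,1e+05,2.8,,"0;-1","PFECA",5,TRUE
"adona","4,8-Dioxa-3H-perfluorononanoic acid","ADONA","919005-14-4","C7H2F12O4",378.06,3.3,1e+05,1,,"0;-1","PFECA",5,TRUE
"clpfaes_8_2","8:2 Chlorinated polyfluoroalkyl ether sulfonic acid","8:2 Cl-PFAES","83329-89-9","C10HClF20O4S",632.58,6.8,20,-3,,"0;-1","PFAES",10,TRUE
"ftoh_4_2","4:2 Fluorotelomer alcohol","4:2 FTOH","2043-47-2","C6H5F9O",264.09,3.1,970,,,"0","FTOH",4,FALSE
"ftoh_6_2","6:2 Fluorotelomer alcohol","6:2 FTOH","647-42-7","C8H5F13O",364.1,4.5,150,,,"0","FTOH",6,FALSE
"ftoh_8_2","8:2 Fluorotelomer alcohol","8:2 FTOH","678-39-7","C10H5F17O",464.12,5.9,19,,,"0","FTOH",8,FALSE
"ftoh_10_2","10:2 Fluorotelomer alcohol","10:2 FTOH","865-86-1","C12H5F21O",564.13,7.3,2.4,,,"0","FTOH",10,FALSE
"fts_4_2","4:2 Fluorotelomer sulfonic acid","4:2 FTS","757124-72-4","C6H5F9O3S",328.14,2.7,10000,-2.5,,"0;-1","FTS",4,TRUE
"fts_6_2","6:2 Fluorotelomer sulfonic acid","6:2 FTS","27619-97-2","C8H5F13O3S",428.16,4.1,2000,-2.5,,"0;-1","FTS",6,TRUE
"fts_8_2","8:2 Fluorotelomer sulfonic acid","8:2 FTS","39108-34-4","C10H5F17O3S",528.17,5.5,300,-2.5,,"0;-1","FTS",8,TRUE
"ftsab_6_2","6:2 Fluorotelomer sulfonamide betaine","6:2 FtSaB","","C15H19F13N2O4S",570.36,4.2,10000,,,"0","cationic_zwitterionic",6,TRUE
"ftsab_8_2","8:2 Fluorotelomer sulfonamide betaine","8:2 FtSaB","","C17H19F17N2O4S",670.38,5.6,3000,,,"0","cationic_zwitterionic",8,TRUE
"ftsab_10_2","10:2 Fluorotelomer sulfonamide betaine","10:2 FtSaB","","C19H19F21N2O4S",770.39,7,1000,,,"0","cationic_zwitterionic",10,TRUE
"ftsaam_6_2","6:2 Fluorotelomer sulfonamide amine","6:2 FtSaAm","","C13H17F13N2O2S",512.32,4.6,5000,9.2,,"1;0","cationic_zwitterionic",6,TRUE
"pfosb","Perfluorooctane sulfonamido betaine","PFOSB","","C14H15F17N2O4S",630.31,5.8,2000,,,"0","cationic_zwitterionic",8,TRUE
"pfoab","Perfluorooctane amido betaine","PFOAB","","C15H17F15N2O3",558.28,4.9,5000,,,"0","cationic_zwitterionic",7,TRUE
"pfoaams","Perfluorooctane amido ammonium salt","PFOAAmS","","C14H19F15N2O",516.29,4.6,5000,,,"1","cationic_zwitterionic",7,TRUE
"amprfhxsa","N-Aminopropyl perfluorohexane sulfonamide","AmPr-FHxSA","","C9H9F13N2O2S",456.22,3.8,10000,6.3,9.8,"1;0;-1","cationic_zwitterionic",6,TRUE
"tamprfhxsa","N-Trimethylammoniumpropyl perfluorohexane sulfonamide","TAmPr-FHxSA","","C12H15F13N2O2S",498.3,4,10000,6.3,,"1;0","cationic_zwitterionic",6,TRUE
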