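"experiment","treatment","dilution_factor","replicate","timepoint","cells_per_ml"
"synthExp1","protists",0.25,1,"T0",1008720.04851097
"synthExp1","protists",0.25,1,"T12",2184371.39299107
"synthExp1","protists",0.25,2,"T0",980465.561721329
"synthExp1","protists",0.25,2,"T12",2209224.28201305
"synthExp1","protists",0.5,1,"T0",1155485.71617074
"synthExp1","protists",0.5,1,"T12",1953278.90663
"synthExp1","protists",0.5,2,"T0",1079719.67380552
"synthExp1","protists",0.5,2,"T12",1963751.70979486
"synthExp1","protists",0.75,1,"T0",1020998.5648005
"synthExp1","protists",0.75,1,"T12",1571841.61721216
"synthExp1","protists",0.75,2,"T0",965679.472360677
"synthExp1","protists",0.75,2,"T12",1554264.62295211
"synthExp1","protists",1,1,"T0",975984.582669771
"synthExp1","protists",1,1,"T12",1263368.40020688
"synthExp1","protists",1,2,"T0",1026061.60067147
"synthExp1","protists",1,2,"T12",1275881.19029138
"synthExp1","protists_viruses",0.25,1,"T0",1021498.22467879
"synthExp1","protists_viruses",0.25,1,"T12",4308816.1510322
"synthExp1","protists_viruses",0.25,2,"T0",1037780.18140446
"synthExp1","protists_viruses",0.25,2,"T12",3839129.69225022
"synthExp1","protists_viruses",0.5,1,"T0",1005651.65108653
"synthExp1","protists_viruses",0.5,1,"T12",2891999.02573026
"synthExp1","protists_viruses",0.5,2,"T0",1008267.85141318
"synthExp1","protists_viruses",0.5,2,"T12",2686243.04803291
"synthExp1","protists_viruses",0.75,1,"T0",1066979.79778698
"synthExp1","protists_viruses",0.75,1,"T12",1800981.09961347
"synthExp1","protists_viruses",0.75,2,"T0",957486.627011159
"synthExp1","protists_viruses",0.75,2,"T12",1852909.45573675
"synthExp1","protists_viruses",1,1,"T0",1042166.41976419
"synthExp1","protists_viruses",1,1,"T12",1452499.11265114
"synthExp1","protists_viruses",1,2,"T0",1020547.43104097
"synthExp1","protists_viruses",1,2,"T12",1333068.29168581
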