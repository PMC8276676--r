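{"disease":"psoriasis","species":[{"id":"IL17A","role":"deg","members":[],"initial":0.5},{"id":"IL17F","role":"deg","members":[],"initial":0.5},{"id":"IL17D","role":"deg","members":[],"initial":0.5},{"id":"IL17RE","role":"deg","members":[],"initial":0.5},{"id":"IL17RA","role":"gene","members":[],"initial":0.5},{"id":"C1","role":"complex","members":["HSP90AA1","TRAF3IP2"],"initial":0.5},{"id":"TRAF6","role":"gene","members":[],"initial":0.5},{"id":"C2","role":"complex","members":["TAB2","TAB3","MAP3K7"],"initial":0.5},{"id":"MKK","role":"gene","members":[],"initial":0.5},{"id":"NFKB","role":"gene","members":[],"initial":0.5},{"id":"MAPKs","role":"deg","members":["MAPK13","MAPK14"],"initial":0.5},{"id":"MAPKs_active","role":"gene","members":[],"initial":0,"fixed":true},{"id":"AP1","role":"complex","members":["FOSL1","FOS"],"initial":0.5},{"id":"chemokines","role":"deg","members":["CXCL1","CXCL2","CXCL5","CXCL8","CXCL10","CCL2","CCL7","CCL20"],"initial":0.5},{"id":"chemokines_secreted","role":"gene","members":[],"initial":0,"fixed":true},{"id":"antimicrobial","role":"deg","members":["S100A7","S100A8","S100A9","LCN2"],"initial":0.5},{"id":"tissue_remodeling","role":"deg","members":["MMP1","MMP9"],"initial":0.5},{"id":"MMPs_active","role":"gene","members":[],"initial":0,"fixed":true},{"id":"IL1B","role":"deg","members":[],"initial":0.5},{"id":"IFNG","role":"deg","members":[],"initial":0.5},{"id":"C3","role":"inhibitor","members":["ANAPC5","TNFAIP3"],"initial":0.5},{"id":"IKBKE","role":"inhibitor","members":[],"initial":0.5},{"id":"autoimmune_pathology","role":"process","members":[],"initial":0},{"id":"neutrophil_recruitment","role":"process","members":[],"initial":0},{"id":"immunity_extracellular_pathogens","role":"process","members":[],"initial":0}],"edges":[{"kind":"activation","source":"IL17A","target":"IL17RA","k":1.2},{"kind":"activation","source":"IL17F","target":"IL17RA","k":1.2},{"kind":"activation","source":"IL17D","target":"IL17RE","k":1.2},{"kind":"activation","source":"IL17RA","target":"C1","k":1.2},{"kind":"activation","source":"IL17RE","target":"C1","k":1.2},{"kind":"activation","source":"C1","target":"TRAF6","k":1.2},{"kind":"activation","source":"TRAF6","target":"C2","k":1.2},{"kind":"activation","source":"C2","target":"NFKB","k":1.2},{"kind":"activation","source":"C2","target":"MKK","k":1.2},{"kind":"activation","source":"chemokines","target":"chemokines_secreted","k":2},{"kind":"catalysis","source":"MKK","substrate":"MAPKs","target":"MAPKs_active","k":0.45},{"kind":"catalysis","source":"MAPKs_active","substrate":"tissue_remodeling","target":"MMPs_active","k":0.22},{"kind":"drive","source":"MAPKs_active","target":"AP1","k":4.5,"m":2},{"kind":"drive","source":"NFKB","target":"chemokines","k":0.15,"m":1},{"kind":"drive","source":"NFKB","target":"antimicrobial","k":0.1,"m":1},{"kind":"inhibition","source":"C3","target":"TRAF6","k":2},{"kind":"inhibition","source":"IKBKE","target":"C1","k":0.3},{"kind":"decay","source":"MKK","k":0.8},{"kind":"decay","source":"MAPKs_active","k":1.1},{"kind":"decay","source":"AP1","k":8},{"kind":"decay","source":"chemokines_secreted","k":1.5},{"kind":"decay","source":"antimicrobial","k":0.8},{"kind":"decay","source":"MMPs_active","k":0.26},{"kind":"decay","source":"IL1B","k":0.8},{"kind":"decay","source":"IFNG","k":0.8},{"kind":"decay","source":"NFKB","k":0.6},{"kind":"drive","source":"AP1","target":"autoimmune_pathology","k":0.1841730032,"m":2},{"kind":"drive","source":"AP1","target":"neutrophil_recruitment","k":0.1841730032,"m":2},{"kind":"drive","source":"AP1","target":"immunity_extracellular_pathogens","k":0.1841730032,"m":2},{"kind":"drive","source":"chemokines_secreted","target":"autoimmune_pathology","k":0.1023183351,"m":3},{"kind":"drive","source":"chemokines_secreted","target":"neutrophil_recruitment","k":0.1023183351,"m":3},{"kind":"drive","source":"chemokines_secreted","target":"immunity_extracellular_pathogens","k":0.1023183351,"m":3},{"kind":"drive","source":"MMPs_active","target":"autoimmune_pathology","k":0.1432456692,"m":3},{"kind":"drive","source":"MMPs_active","target":"neutrophil_recruitment","k":0.1432456692,"m":3},{"kind":"drive","source":"MMPs_active","target":"immunity_extracellular_pathogens","k":0.1432456692,"m":3},{"kind":"drive","source":"antimicrobial","target":"autoimmune_pathology","k":0.0040927334,"m":1},{"kind":"drive","source":"antimicrobial","target":"neutrophil_recruitment","k":0.0040927334,"m":1},{"kind":"drive","source":"antimicrobial","target":"immunity_extracellular_pathogens","k":0.0040927334,"m":1},{"kind":"drive","source":"IL1B","target":"autoimmune_pathology","k":0.0040927334,"m":1},{"kind":"drive","source":"IL1B","target":"neutrophil_recruitment","k":0.0040927334,"m":1},{"kind":"drive","source":"IL1B","target":"immunity_extracellular_pathogens","k":0.0040927334,"m":1},{"kind":"drive","source":"IFNG","target":"autoimmune_pathology","k":0.0040927334,"m":1},{"kind":"drive","source":"IFNG","target":"neutrophil_recruitment","k":0.0040927334,"m":1},{"kind":"drive","source":"IFNG","target":"immunity_extracellular_pathogens","k":0.0040927334,"m":1}]}
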