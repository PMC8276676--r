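{"disease":"cSCC","species":[{"id":"IL17A","role":"gene","members":[],"initial":0.5},{"id":"IL17F","role":"gene","members":[],"initial":0.5},{"id":"IL17RA","role":"gene","members":[],"initial":0.5},{"id":"C1","role":"complex","members":["HSP90AA1","TRAF3IP2"],"initial":0.5},{"id":"TRAF6","role":"deg","members":[],"initial":0.5},{"id":"C2","role":"complex","members":["TAB2","TAB3","MAP3K7"],"initial":0.5},{"id":"MKK","role":"gene","members":[],"initial":0.5},{"id":"NFKB","role":"gene","members":[],"initial":0.5},{"id":"IKBKG","role":"deg","members":[],"initial":0.5},{"id":"TRADD","role":"deg","members":[],"initial":0.5},{"id":"MAPKs","role":"deg","members":["MAPK3","MAPK9","MAPK10","MAPK11","MAPK14"],"initial":0.5},{"id":"MAPKs_active","role":"gene","members":[],"initial":0,"fixed":true},{"id":"AP1","role":"complex","members":["FOSL1","JUN"],"initial":0.5},{"id":"JUND","role":"deg","members":[],"initial":0.5},{"id":"chemokines","role":"deg","members":["CXCL1","CXCL2","CXCL8","CCL20"],"initial":0.5},{"id":"chemokines_secreted","role":"gene","members":[],"initial":0,"fixed":true},{"id":"CXCL3","role":"deg","members":[],"initial":0.5},{"id":"antimicrobial","role":"deg","members":["DEFB4A","DEFB4B","S100A7","S100A8","S100A9","LCN2"],"initial":0.5},{"id":"tissue_remodeling","role":"deg","members":["MMP1","MMP3","MMP9","MMP13"],"initial":0.5},{"id":"SRSF1","role":"deg","members":[],"initial":0.5},{"id":"ELAVL1","role":"deg","members":[],"initial":0.5},{"id":"IL1B","role":"deg","members":[],"initial":0.5},{"id":"TNF","role":"deg","members":[],"initial":0.5},{"id":"TNF_secreted","role":"gene","members":[],"initial":0,"fixed":true},{"id":"TRAF2","role":"inhibitor","members":[],"initial":0.5},{"id":"IKBKE","role":"inhibitor","members":[],"initial":0.5},{"id":"autoimmune_pathology","role":"process","members":[],"initial":0},{"id":"neutrophil_recruitment","role":"process","members":[],"initial":0},{"id":"immunity_extracellular_pathogens","role":"process","members":[],"initial":0}],"edges":[{"kind":"activation","source":"IL17A","target":"IL17RA","k":0.45},{"kind":"activation","source":"IL17F","target":"IL17RA","k":0.45},{"kind":"activation","source":"IL17RA","target":"C1","k":0.45},{"kind":"activation","source":"C1","target":"TRAF6","k":0.45},{"kind":"activation","source":"TRAF6","target":"C2","k":0.45},{"kind":"activation","source":"C2","target":"NFKB","k":0.45},{"kind":"activation","source":"C2","target":"MKK","k":0.45},{"kind":"activation","source":"IKBKG","target":"NFKB","k":0.45},{"kind":"activation","source":"TRADD","target":"NFKB","k":0.45},{"kind":"activation","source":"JUND","target":"AP1","k":0.3},{"kind":"activation","source":"chemokines","target":"chemokines_secreted","k":2},{"kind":"activation","source":"TNF","target":"TNF_secreted","k":2},{"kind":"catalysis","source":"MKK","substrate":"MAPKs","target":"MAPKs_active","k":0.9},{"kind":"drive","source":"MAPKs_active","target":"AP1","k":5,"m":2},{"kind":"drive","source":"NFKB","target":"chemokines","k":0.15,"m":1},{"kind":"drive","source":"NFKB","target":"antimicrobial","k":0.1,"m":1},{"kind":"drive","source":"SRSF1","target":"chemokines","k":0.05,"m":1},{"kind":"drive","source":"ELAVL1","target":"chemokines","k":0.05,"m":1},{"kind":"inhibition","source":"TRAF2","target":"TRAF6","k":1},{"kind":"inhibition","source":"IKBKE","target":"C1","k":0.3},{"kind":"decay","source":"MKK","k":0.8},{"kind":"decay","source":"MAPKs_active","k":0.22},{"kind":"decay","source":"AP1","k":8},{"kind":"decay","source":"chemokines_secreted","k":1.2},{"kind":"decay","source":"TNF_secreted","k":1},{"kind":"decay","source":"antimicrobial","k":0.8},{"kind":"decay","source":"tissue_remodeling","k":0.8},{"kind":"decay","source":"IL1B","k":0.8},{"kind":"decay","source":"NFKB","k":0.6},{"kind":"decay","source":"SRSF1","k":0.8},{"kind":"decay","source":"ELAVL1","k":0.8},{"kind":"decay","source":"CXCL3","k":0.8},{"kind":"drive","source":"AP1","target":"autoimmune_pathology","k":0.211919461,"m":2},{"kind":"drive","source":"AP1","target":"neutrophil_recruitment","k":0.211919461,"m":2},{"kind":"drive","source":"AP1","target":"immunity_extracellular_pathogens","k":0.211919461,"m":2},{"kind":"drive","source":"TNF_secreted","target":"autoimmune_pathology","k":0.353199102,"m":3},{"kind":"drive","source":"TNF_secreted","target":"neutrophil_recruitment","k":0.353199102,"m":3},{"kind":"drive","source":"TNF_secreted","target":"immunity_extracellular_pathogens","k":0.353199102,"m":3},{"kind":"drive","source":"chemokines_secreted","target":"autoimmune_pathology","k":0.014127964,"m":1},{"kind":"drive","source":"chemokines_secreted","target":"neutrophil_recruitment","k":0.014127964,"m":1},{"kind":"drive","source":"chemokines_secreted","target":"immunity_extracellular_pathogens","k":0.014127964,"m":1},{"kind":"drive","source":"CXCL3","target":"autoimmune_pathology","k":0.014127964,"m":1},{"kind":"drive","source":"CXCL3","target":"neutrophil_recruitment","k":0.014127964,"m":1},{"kind":"drive","source":"CXCL3","target":"immunity_extracellular_pathogens","k":0.014127964,"m":1},{"kind":"drive","source":"antimicrobial","target":"autoimmune_pathology","k":0.014127964,"m":1},{"kind":"drive","source":"antimicrobial","target":"neutrophil_recruitment","k":0.014127964,"m":1},{"kind":"drive","source":"antimicrobial","target":"immunity_extracellular_pathogens","k":0.014127964,"m":1},{"kind":"drive","source":"tissue_remodeling","target":"autoimmune_pathology","k":0.014127964,"m":1},{"kind":"drive","source":"tissue_remodeling","target":"neutrophil_recruitment","k":0.014127964,"m":1},{"kind":"drive","source":"tissue_remodeling","target":"immunity_extracellular_pathogens","k":0.014127964,"m":1},{"kind":"drive","source":"IL1B","target":"autoimmune_pathology","k":0.014127964,"m":1},{"kind":"drive","source":"IL1B","target":"neutrophil_recruitment","k":0.014127964,"m":1},{"kind":"drive","source":"IL1B","target":"immunity_extracellular_pathogens","k":0.014127964,"m":1}]}
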