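"class_name","split","count"
"dyed-lifted-polyps","train",637
"dyed-lifted-polyps","validation",182
"dyed-lifted-polyps","test",93
"normal-z-line","train",582
"normal-z-line","validation",166
"normal-z-line","test",85
"dyed-resection-margins","train",366
"dyed-resection-margins","validation",104
"dyed-resection-margins","test",55
"normal-pylorus","train",569
"normal-pylorus","validation",162
"normal-pylorus","test",83
"normal-cecum","train",682
"normal-cecum","validation",195
"normal-cecum","test",99
"polyps","train",696
"polyps","validation",199
"polyps","test",100
"ulcerative-colitis","train",307
"ulcerative-colitis","validation",87
"ulcerative-colitis","test",45
"esophagitis","train",696
"esophagitis","validation",199
"esophagitis","test",101
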