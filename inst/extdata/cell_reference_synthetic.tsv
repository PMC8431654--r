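cpg_id	CD4T	CD8T	NK	Bcell	Mono	Gran
cg_CD4T_1	90	5	7	9	11	13
cg_CD4T_2	90	12	14	5	7	9
cg_CD8T_1	6	90	10	12	14	5
cg_CD8T_2	13	90	6	8	10	12
cg_NK_1	9	11	90	15	6	8
cg_NK_2	5	7	90	11	13	15
cg_Bcell_1	12	14	5	90	9	11
cg_Bcell_2	8	10	12	90	5	7
cg_Mono_1	15	6	8	10	90	14
cg_Mono_2	11	13	15	6	90	10
cg_Gran_1	7	9	11	13	15	90
cg_Gran_2	14	5	7	9	11	90
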