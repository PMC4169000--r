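# Transcripts characterized in detail in the screen: primary-knockdown
# z-score, DGE class, and in-situ expression-pattern type, transcribed
# from the published summary table. Patterns are normalized to tokens:
# "O (+ endo)" -> O_endo, "A#" -> A, "D/A" -> D_A. The printed name
# "WegAI" is the WegA1 transcript. The orf_complete column is not part
# of the printed table; it defaults to TRUE (synthetic placeholder used
# only as an enrichment filter).
name	wnt3_z	dge_class	pattern	restricted	orf_complete
WegO1	-24.6	1	O	TRUE	TRUE
Znf845	-21.2	2	IE	FALSE	TRUE
DMRT-E	-19.1	2	IE	FALSE	TRUE
HlhIE1	-18.7	1	IE	FALSE	TRUE
Mos3	-18.2	2	IE	FALSE	TRUE
Bra2	-18	1	O	FALSE	TRUE
Sulf	-17.5	1	IE	FALSE	TRUE
FoxA	-16.2	2	IE	FALSE	TRUE
FoxC	-15.5	2	IE	FALSE	TRUE
ZnfO	-14.8	2	O	FALSE	TRUE
Sox15	-14.5	2	IE	FALSE	TRUE
WntX1A	-13.8	1	O	FALSE	TRUE
Akr	-13.6	1	O_endo	FALSE	TRUE
WegIE1	-13.3	2	IE	TRUE	TRUE
HlhIE2	-12.9	2	IE	FALSE	TRUE
Aat	-12.4	1	O_endo	FALSE	TRUE
WegIE2	-12	2	IE	TRUE	TRUE
WegO2	-11.8	1	O	TRUE	TRUE
Myb	-11.4	1	O	FALSE	TRUE
Erg	-11.2	2	IE	FALSE	TRUE
Bra	-10.6	1	O	FALSE	TRUE
FoxQ2c	-8.4	2	IE	FALSE	TRUE
NotumO	-8.4	1	O	FALSE	TRUE
WegO3	-5	1	O_endo	FALSE	TRUE
Gsc	-4.6	1	O	FALSE	TRUE
Botch1	18.1	4	D	FALSE	TRUE
bZip	12	4	D_A	FALSE	TRUE
FoxQ2a	11	3	A	FALSE	TRUE
Dkk	10.2	3	A	FALSE	TRUE
ZnfA	10	3	A	FALSE	TRUE
NotumA	9.3	4	A	FALSE	TRUE
Botch2	8.8	4	D_A	FALSE	TRUE
WegD1	8.2	4	D	TRUE	TRUE
WegA1	8.3	3	A	TRUE	TRUE
Asp	7.9	4	D	FALSE	TRUE
WegD2	7.8	4	D	TRUE	TRUE
Dan1	7.3	3	A	FALSE	TRUE
ZpdA	7.3	4	D_A	FALSE	TRUE
Amt	6.9	4	D	FALSE	TRUE
HD02	7	4	D	FALSE	TRUE
WegA2	6.9	3	A	TRUE	TRUE
Notch	6.7	3	D_A	FALSE	TRUE
UCP	6.8	4	D	FALSE	TRUE
Tbx	6.5	3	A	FALSE	TRUE
sFRP-A	6.2	3	A	FALSE	TRUE
Fz3	5.4	3	A	FALSE	TRUE
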