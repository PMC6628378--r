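comparison	mirna	mirna_log2fc	transcript	mrna_log2fc	description
HRK48/HRK0	Gma-miR1535a	1.57	Glyma.08G264900.2	-2.25	phototropin-2-like
HRK48/HRK0	Gma-miR166u	-1.70	Glyma.18G204800.1	3.42	ammonium transporter AMT2.2
HRK48/HRK0	Gma-miR394a-3p	-2.26	Glyma.14G004300.1	3.71	nudix hydrolase 2-like
HRK48/HRK0	Gma-miR394a-3p	-2.26	Glyma.05G073500.2	7.12	F-box protein SKIP14-like
HRK48/HRK0	Gma-miR4996	1.77	Glyma.U019800.1	-7.57	auxin response factor 4-like
HRK48/HRK0	Gma-miR5374-3p	-2.20	Glyma.17G128200.2	7.21	cyclin-dependent kinase G-2-like
HRK48/HRK0	Novel_miR2	1.19	Glyma.05G167800.2	-3.78	guanosine nucleotide diphosphate dissociation inhibitor 2
HSK48/HSK0	Gma-miR1512b	3.10	Glyma.09G019300.1	-6.94	protein FAR1-RELATED SEQUENCE 6
HSK48/HSK0	Gma-miR1535a	2.22	Glyma.19G036600.2	-7.41	probable leucine-rich repeat receptor-like serine/threonine-protein kinase At5g15730
HSK48/HSK0	Gma-miR166j-3p	-1.25	Glyma.07G016700.2	8.54	homeobox-leucine zipper protein ATHB-15-like isoform X4
HSK48/HSK0	Gma-miR166u	-1.42	Glyma.07G016700.2	8.54	homeobox-leucine zipper protein ATHB-15-like isoform X4
HSK48/HSK0	Gma-miR395g	-1.21	Glyma.14G005800.3	8.16	nuclear pore complex protein NUP96
HSK48/HSK0	Gma-miR395g	-1.21	Glyma.14G005800.4	8.10	nuclear pore complex protein NUP96
HSK48/HSK0	Gma-miR399b	-2.31	Glyma.03G021900.2	7.06	uncharacterized protein LOC100306494 isoform X1
HSK48/HSK0	Gma-miR5761a	2.34	Glyma.11G210400.3	-2.68	glycinol 4-dimethylallyltransferase-like
HSK48/HSK0	Gma-miR9749	-1.30	Glyma.09G236600.3	7.32	lipoate-protein ligase LplJ
HSK48/HSK0	Novel_miR2	3.13	Glyma.05G167800.2	-9.51	guanosine nucleotide diphosphate dissociation inhibitor 2
HRK0/HSK0	Gma-miR156q	-1.10	Glyma.06G238100.1	2.37	squamosa promoter-binding protein 1-like
HRK0/HSK0	Gma-miR319d	1.65	Glyma.08G087400.1	-5.22	uncharacterized protein LOC100778760
HRK0/HSK0	Gma-miR394a-3p	1.66	Glyma.05G073500.2	-7.96	F-box protein SKIP14-like
HRK0/HSK0	Gma-miR396e	3.89	Glyma.13G159700.1	-6.85	hypothetical protein GLYMA_13G159700
HRK0/HSK0	Gma-miR4996	-3.14	Glyma.06G040600.1	9.05	THO complex subunit 5A-like isoform X1
HRK0/HSK0	Gma-miR5769	-1.27	Glyma.02G186100.2	8.96	calcium-transporting ATPase 4, plasma membrane-type-like
HRK0/HSK0	Novel_miR36	1.99	Glyma.07G178800.2	-6.80	pentatricopeptide repeat-containing protein At2g15820, chloroplastic-like
HRK48/HSK48	Gma-miR166b	4.63	Glyma.07G016700.2	-8.54	homeobox-leucine zipper protein ATHB-15-like isoform X4
HRK48/HSK48	Gma-miR166j-3p	1.63	Glyma.07G016700.2	-8.54	homeobox-leucine zipper protein ATHB-15-like isoform X4
HRK48/HSK48	Gma-miR395g	1.38	Glyma.14G005800.3	-8.16	nuclear pore complex protein NUP96
HRK48/HSK48	Gma-miR398b	-1.47	Glyma.01G055700.2	3.19	hypothetical protein GLYMA_01G055700
HRK48/HSK48	Gma-miR4416a	-1.15	Glyma.19G136400.2	7.88	putative calcium-transporting ATPase 11, plasma membrane-type
HRK48/HSK48	Gma-miR4996	-1.73	Glyma.06G040600.1	8.90	THO complex subunit 5A-like
HRK48/HSK48	Gma-miR4996	-1.73	Glyma.07G002800.2	7.50	ubiquitin receptor RAD23b-like
HRK48/HSK48	Gma-miR5761a	-1.30	Glyma.13G004400.1	2.45	zinc transporter 8-like
HRK48/HSK48	Novel_miR36	2.66	Glyma.06G088200.3	-7.97	amino acid permease 6-like
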