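gene_id	biotype
Cst9	protein_coding
Cox8c	protein_coding
Ddx4	protein_coding
Tuba3b	protein_coding
Rbakdn	lncRNA
4930449C09Rik	lncRNA
Pttg1ip2	protein_coding
Capza3	protein_coding
Prr27	protein_coding
Piwil1	protein_coding
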