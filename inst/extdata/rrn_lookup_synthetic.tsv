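genus	mean_copies
Phenylobacterium	1.0
Pelagibacter	1.0
Nitrosomonas	1.1
Nitrospira	1.3
Methylobacterium	1.8
Sphingomonas	2.0
Caulobacter	2.0
Rhodopseudomonas	2.3
Bradyrhizobium	2.4
Hyphomicrobium	2.6
Acidovorax	3.0
Sphingobium	3.0
Rhodobacter	3.2
Novosphingobium	3.4
Pseudomonas	4.4
Janthinobacterium	4.6
Flavobacterium	5.0
Duganella	5.3
Shewanella	6.1
Rheinheimera	6.5
Escherichia	7.0
Aeromonas	8.2
Azospirillum	9.0
Clostridium	9.0
Bacillus	9.9
Paenibacillus	11.2
Vibrio	11.8
Brevibacillus	12.4
Photobacterium	14.1
Clostridioides	15.6
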