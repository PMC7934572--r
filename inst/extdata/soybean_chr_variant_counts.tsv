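# Per-chromosome variant counts for the 198-accession soybean resequencing panel
# (raw GATK joint-genotyping output and the post-filtering call set).
chrom	raw_snp	raw_indel	raw_total	filtered_snp	filtered_indel	filtered_total
Chr01	809046	139387	948433	519110	133213	652323
Chr02	685281	138448	823729	464550	133805	598355
Chr03	918813	165558	1084371	581996	160415	742411
Chr04	858671	147249	1005920	564337	141912	706249
Chr05	560582	110072	670654	361072	105493	466565
Chr06	925223	171679	1096902	579010	166158	745168
Chr07	712969	143049	856018	463300	138337	601637
Chr08	693324	147969	841293	456798	143504	600302
Chr09	743949	141684	885633	481385	136143	617528
Chr10	714099	134919	849018	462054	129213	591267
Chr11	438702	95978	534680	303411	92734	396145
Chr12	595004	115856	710860	391525	111748	503273
Chr13	722750	160407	883157	481921	156154	638075
Chr14	902138	151259	1053397	590557	145723	736280
Chr15	1048862	175748	1224610	648774	170120	818894
Chr16	861304	165506	1026810	526504	160445	686949
Chr17	642407	125991	768398	425846	122022	547868
Chr18	1272177	224567	1496744	794961	217759	1012720
Chr19	804396	144788	949184	512977	139773	652750
Chr20	767005	136478	903483	506619	131009	637628
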