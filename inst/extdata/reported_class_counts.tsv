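contrast	measure	class	affected	total
bvFTD_vs_control	FA	rich_club	29	179
bvFTD_vs_control	FA	feeder	78	390
bvFTD_vs_control	FA	local	51	173
EOAD_vs_control	fiber_density	rich_club	23	195
EOAD_vs_control	fiber_density	feeder	12	442
EOAD_vs_control	fiber_density	local	4	206
EOAD_vs_control	nodal_degree	rich_club	13	26
EOAD_vs_control	nodal_degree	nonrich	6	42
bvFTD_vs_EOAD	fiber_density	rich_club	5	179
bvFTD_vs_EOAD	fiber_density	feeder	9	390
bvFTD_vs_EOAD	fiber_density	local	11	173
EOAD_vs_bvFTD	fiber_density	rich_club	14	195
EOAD_vs_bvFTD	fiber_density	feeder	7	442
EOAD_vs_bvFTD	fiber_density	local	3	206
MMSE_assoc	MD	rich_club	29	196
MMSE_assoc	MD	feeder	58	436
MMSE_assoc	MD	local	28	196
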