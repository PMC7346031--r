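sample	chrom	loc.start	loc.end	num.mark	seg.mean	copy_status
T01	chr8	128700000	128800000	20	0.5	4
T02	chr8	128700000	128800000	9	0.5	4
T03	chr8	128700000	128800000	10	0.2	4
T04	chr8	128700000	128800000	10	0.21	3
T05	chr8	128700000	128800000	10	0.21	2
T06	chr8	128700000	128800000	10	0.21	NA
T07	chr17	7500000	7600000	20	-0.5	0
T08	chr17	7500000	7600000	9	-0.5	0
T09	chr17	7500000	7600000	10	-0.2	1
T10	chr17	7500000	7600000	10	-0.21	1
T11	chr17	7500000	7600000	10	-0.21	2
T12	chr17	7500000	7600000	10	-0.21	NA
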