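# Reported candidate domestication-sweep windows from a farmed-vs-wild
# Atlantic salmon pool-seq contrast (150 kb windows, 75 kb step).
# zhp_farmed / zhp_wild are the published per-group ZHp values (2 decimals);
# delta_reported is the published dZHp. Because the published dZHp was
# computed from unrounded ZHp, recomputing it from the 2-decimal ZHp pair
# can differ by +/- 0.01 (display rounding), e.g. the vcan window
# (chr20:9375001) prints 5.89 but recomputes as 5.90, and chr20:53700001
# prints 4.79 but recomputes as 4.78.
chrom	start	end	zhp_farmed	zhp_wild	delta_reported
20	9375001	9525000	-2.72	3.18	5.89
20	9300001	9450000	-3.00	2.79	5.79
12	27975001	28125000	-1.64	3.64	5.28
20	53625001	53775000	-1.84	3.26	5.10
27	26325001	26475000	-2.50	2.53	5.02
20	32775001	32925000	-2.57	2.44	5.00
20	53700001	53850000	-1.74	3.04	4.79
9	95175001	95325000	-2.36	2.20	4.55
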