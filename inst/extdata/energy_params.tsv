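key	value
stack.AU.AU	-0.93
stack.AU.CG	-2.24
stack.AU.GC	-2.08
stack.AU.GU	-0.55
stack.AU.UA	-1.1
stack.AU.UG	-1.36
stack.CG.AU	-2.11
stack.CG.CG	-3.26
stack.CG.GC	-2.36
stack.CG.GU	-1.41
stack.CG.UA	-2.08
stack.CG.UG	-2.11
stack.GC.AU	-2.35
stack.GC.CG	-3.42
stack.GC.GC	-3.26
stack.GC.GU	-1.53
stack.GC.UA	-2.24
stack.GC.UG	-2.51
stack.GU.AU	-0.91
stack.GU.CG	-2.51
stack.GU.GC	-2.11
stack.GU.GU	-0.5
stack.GU.UA	-1.36
stack.GU.UG	0.47
stack.UA.AU	-1.33
stack.UA.CG	-2.35
stack.UA.GC	-2.11
stack.UA.GU	-1
stack.UA.UA	-0.93
stack.UA.UG	-0.91
stack.UG.AU	-1
stack.UG.CG	-1.53
stack.UG.GC	-1.41
stack.UG.GU	0.3
stack.UG.UA	-0.55
stack.UG.UG	-0.5
hairpin_a	4.5
hairpin_b	1.6
interior_a	3.2
interior_b	1.1
multiloop	3.4
min_loop	3
max_interior	12
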