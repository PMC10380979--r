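name	sensitivity	specificity	coverage
synth01	0.927	0.561	0.58
synth02	0.969	0.982	0.92
synth03	0.669	0.776	0.887
synth04	0.847	0.77	0.843
synth05	0.979	0.604	0.971
synth06	0.838	0.815	0.943
synth07	0.663	0.722	0.699
synth08	0.763	0.912	0.468
synth09	0.817	0.567	0.757
synth10	0.747	0.507	0.629
synth11	0.655	0.971	0.639
synth12	0.697	0.999	0.876
synth13	0.717	0.689	0.935
synth14	0.593	0.627	0.402
synth15	0.982	0.855	0.857
synth16	0.628	0.741	0.852
synth17	0.959	0.682	0.916
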