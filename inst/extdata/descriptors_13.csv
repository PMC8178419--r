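descriptor_id,description,citation,A,R,N,D,C,Q,E,G,H,I,L,K,M,F,P,S,T,W,Y,V
ZIMJ680104,Isoelectric point,Zimmerman et al. 1968 (best-match accession),6.00,10.76,5.41,2.77,5.05,5.65,3.22,5.97,7.59,6.02,5.98,9.74,5.74,5.48,6.30,5.68,5.66,5.89,5.66,5.96
FAUJ880103,Normalized van der Waals volume,Fauchere et al. 1988 (best-match accession),1.00,6.13,2.95,2.78,2.43,3.95,3.78,0.00,4.66,4.00,4.00,4.77,4.43,5.89,2.72,1.60,2.60,8.08,6.47,3.00
SYNAHB0103,Alpha-helix indices for beta-proteins,curated scale (synthetic best-match values),1.29,0.96,0.90,1.04,1.11,1.27,1.44,0.56,1.22,0.97,1.30,1.23,1.47,1.07,0.52,0.82,0.82,0.99,0.72,0.91
SYNBSB0104,Beta-strand indices for beta-proteins,curated scale (synthetic best-match values),0.90,0.99,0.76,0.72,1.24,1.18,0.75,0.92,1.08,1.45,1.02,0.77,0.97,1.32,0.64,0.95,1.21,1.14,1.25,1.49
SYNSCS0105,Side-chain contribution to protein stability,curated scale (synthetic best-match values),0.52,0.63,0.38,0.34,1.12,0.55,0.45,0.00,0.87,1.32,1.28,0.51,1.15,1.86,0.36,0.28,0.52,1.94,1.46,1.09
SYNKBP0106,Stability scale from knowledge-based atom-atom potential,curated scale (synthetic best-match values),0.60,0.55,0.50,0.35,0.45,0.60,0.50,0.70,1.10,0.55,0.65,0.45,0.80,1.55,0.65,0.55,0.60,1.85,1.65,0.50
KYTJ820101,Hydropathy index,Kyte-Doolittle 1982 (best-match accession),1.8,-4.5,-3.5,-3.5,2.5,-3.5,-3.5,-0.4,-3.2,4.5,3.8,-3.9,1.9,2.8,-1.6,-0.8,-0.7,-0.9,-1.3,4.2
CHOP780101,Normalized frequency of turn,Chou-Fasman 1978 (best-match accession),0.66,0.95,1.56,1.46,1.19,0.98,0.74,1.56,0.95,0.47,0.59,1.01,0.60,0.60,1.52,1.43,0.96,0.96,1.14,0.50
SYNFEB0109,Free energy in beta-strand region,curated scale (synthetic best-match values),0.26,0.14,0.46,0.45,0.12,0.19,0.33,1.20,0.33,-0.26,0.10,0.22,0.12,-0.04,1.85,0.22,-0.06,0.04,-0.01,-0.22
SYNFEA0110,Free energy in alpha-helical region,curated scale (synthetic best-match values),-0.18,0.01,0.30,0.19,0.33,0.03,-0.11,0.69,0.19,0.26,-0.09,0.02,-0.05,0.20,1.30,0.30,0.38,0.21,0.33,0.42
ZIMJ680103,Polarity,Zimmerman et al. 1968 (best-match accession),0.00,52.00,3.38,49.70,1.48,3.53,49.90,0.00,51.60,0.13,0.13,49.50,1.43,0.35,1.58,1.67,1.66,2.10,1.61,0.13
SYNSCI0112,Side chain interaction parameter,curated scale (synthetic best-match values),1.5,3.0,4.2,6.3,1.2,5.5,6.0,1.0,2.2,1.8,2.0,6.9,1.6,1.4,5.8,2.6,2.1,1.7,2.4,1.9
SYNAAD0113,Amino acid distribution,curated scale (synthetic best-match values),8.3,5.7,4.4,5.3,1.7,4.0,6.2,7.2,2.2,5.2,9.0,5.7,2.4,3.9,5.1,6.9,5.8,1.3,3.2,6.6
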