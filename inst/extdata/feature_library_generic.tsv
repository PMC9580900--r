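# plasmidkit generic feature library, format v1
# name <TAB> pattern <TAB> color <TAB> gb_type <TAB> strand_policy
# pattern language: IUPAC letters (lowercase = gap), '#' >=0 bases,
# '+' >=1 base, context before '<' / after '>'
T7 promoter	TAATACGACTCACTATAG	#34a853	promoter	both
SP6 promoter	ATTTAGGTGACACTATAG	#fbbc04	promoter	both
M13 fwd	GTAAAACGACGGCCAGT	#4285f4	primer_bind	both
M13 rev	CAGGAAACAGCTATGAC	#ea4335	primer_bind	both
lac operator	AATTGTGAGCGGATAACAATT	#9900cc	protein_bind	both
demo gap feature	TTcgTT	#00bbbb	misc_feature	top
demo context feature	AA<GGWCC>TT	#bb0077	misc_feature	both
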