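column	type	coding	description
id	character	unique	Opaque patient identifier
age	integer	years	Age at surgery
sex	character	male/female	Sex
lauren	character	intestinal/diffuse/mixed	Lauren histological classification
location	character	stomach/egj	Primary tumor location (stomach or esophagogastric junction)
radicality	character	R0/R1/R2	Surgical resection radicality
lymphadenectomy	character	D0/D1/D2/NR	Extent of lymphadenectomy (NR = not related)
pt	character	Tis/T1/T2/T3/T4	Pathological tumor depth
pn	character	N0/N1/N2/N3	Pathological nodal status
stage	character	0/IA/IB/II/IIIA/IIIB/IVM0/IVM1	AJCC 6th edition TNM stage group
adjuvant	character	surgery_alone/chemoradiotherapy	Adjuvant treatment
time_months	numeric	months >= 0	Overall survival time from surgery to death or last contact
event	integer	0/1	1 = death from any cause, 0 = censored
postop_death	integer	0/1	Death during the postoperative period (excluded from survival analysis)
her1_membrane	integer	0-3 or empty	HER1 membrane IHC staining score
her1_cytoplasm	integer	0-3 or empty	HER1 cytoplasm IHC staining score
her2_membrane	integer	0-3 or empty	HER2 membrane IHC staining score (membrane only per consensus scoring)
her3_membrane	integer	0-3 or empty	HER3 membrane IHC staining score (near-absent in gastric tumors)
her3_cytoplasm	integer	0-3 or empty	HER3 cytoplasm IHC staining score
her4_membrane	integer	0-3 or empty	HER4 membrane IHC staining score
her4_cytoplasm	integer	0-3 or empty	HER4 cytoplasm IHC staining score
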