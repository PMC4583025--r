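protein_id	klass	realized_enrich_effect	realized_insulin_effect
P00001	true_gsv	3.10761866879141	1.46436239226635
P00002	true_gsv	2.9966863564603	1.55930527870374
P00003	true_gsv	2.71780525121442	1.17939218662356
P00004	contaminant	0	0
P00005	background_binder	0	0
P00006	background_binder	0	0
P00007	background_binder	0	0
P00008	background_binder	0	0
P00009	background_binder	0	0
P00010	background_binder	0	0
P00011	background_binder	0	0
P00012	background_binder	0	0
P00013	background_binder	0	0
P00014	background_binder	0	0
P00015	background_binder	0	0
P00016	background_binder	0	0
P00017	background_binder	0	0
P00018	background_binder	0	0
P00019	background_binder	0	0
P00020	background_binder	0	0
P00021	background_binder	0	0
P00022	background_binder	0	0
P00023	background_binder	0	0
P00024	background_binder	0	0
P00025	background_binder	0	0
P00026	background_binder	0	0
P00027	background_binder	0	0
P00028	background_binder	0	0
P00029	background_binder	0	0
P00030	background_binder	0	0
P00031	background_binder	0	0
P00032	background_binder	0	0
P00033	background_binder	0	0
P00034	background_binder	0	0
P00035	background_binder	0	0
P00036	background_binder	0	0
P00037	background_binder	0	0
P00038	background_binder	0	0
P00039	background_binder	0	0
P00040	background_binder	0	0
P00041	background_binder	0	0
P00042	background_binder	0	0
P00043	background_binder	0	0
P00044	background_binder	0	0
P00045	background_binder	0	0
P00046	background_binder	0	0
P00047	background_binder	0	0
P00048	background_binder	0	0
P00049	background_binder	0	0
P00050	background_binder	0	0
P00051	background_binder	0	0
P00052	background_binder	0	0
P00053	background_binder	0	0
P00054	background_binder	0	0
P00055	background_binder	0	0
P00056	background_binder	0	0
P00057	background_binder	0	0
P00058	background_binder	0	0
P00059	background_binder	0	0
P00060	background_binder	0	0
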