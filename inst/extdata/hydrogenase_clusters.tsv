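name	locus_range	total_cds
Mrp-Mbh	A7C91_RS04230-04165	14
Fdh1-Mfh1-Mnh1	A7C91_RS06945-07020	16
Fdh2-Mfh2-Mnh2	A7C91_RS04320-04240	17
F420-reducing hydrogenase	A7C91_RS_04340-04330	3
SHI	A7C91_RS08740-08725	4
SHII	A7C91_RS06200-06185	4
Mrp-Mbs	A7C91_RS08510-08450	13
Nsr	A7C91_RS06865	1
SurR	A7C91_RS07565	1
Pdo	A7C91_RS07570	1
Nfn I	A7C91_RS06205-6210	2
Nfn II/Xfn	A7C91_RS02315-2310	2
Nfn III	A7C91_RS02425-2430	2
Fdh3	A7C91_RS08745-08770	6
RNR	A7C91_RS02975	1
ATP synthase	A7C91_RS03355-03315	9
TrxR	A7C91_RS04130	1
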