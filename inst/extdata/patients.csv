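patient_id,age_range,onset_age,ocb,pregnancy,lesions,spinal_lesions,treatments
1070,20-29,20,yes,,2007-03:3;2007-06:5;2010-10:77;2010-12:82;2013-05:59;2015-06:41,2013-05:6;2015-06:7,2007-09:ifnb1a;2013-05:fingolimod;2015-12:natalizumab
3736,30-39,30,yes,2015-11/2016-08,2014-09:22;2015-01:28,N/D,2015-02..2015-12:natalizumab;2016-09:natalizumab
2789,30-39,33,yes,2012-10/2013-07;2015-11/2016-08,2013-11:9;2013-12:9;2014-09:9;2017-01:14,N/D,2017-02:teriflunomide
5793,20-29,26,yes,,2015-08:20;2015-09:22;2016-01:28,N/D,2016-06:natalizumab
2070,30-39,31,no,,2014-10:23;2015-03:37;2016-01:33,N/D,2014-12:ifnb1a
2961,30-39,29,no,,2015-03:49;2016-03:43;2017-04:65,N/D,N/A
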