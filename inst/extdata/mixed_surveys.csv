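record_id,form,linked_screener_id,client_timestamp,server_timestamp,submit_instant,completion_minutes,counties_marked,zip,heard_source,captcha_passed,honeypot_value,email,phone,postal_address,ip_hash,child_age_years,child_grade,sb_weak,sb_attention,open_text,item_01,item_02,item_03,item_04,item_05,item_06,item_07,item_08,item_09,item_10,item_11,item_12,item_13,item_14,item_15,item_16,item_17,item_18,item_19,item_20,item_dupcheck,item_dupcheck_rep
R00001,survey,S00001,2022-01-27T12:27:33+0000,2022-01-27T12:27:33+0000,2022-01-27T12:27:33+0000,18.695,County19,20694,community_flyer,TRUE,,martha.mason85@mailbox.net,410-335-7114,101 Lake St,h373a1bcc,5,0,the man,strongly agree,art cleaning reading science flexibility answers school policy mornings,d,d,a,a,b,b,b,d,d,a,c,a,c,d,c,d,c,a,d,d,yes,yes
R00002,survey,S00002,2022-01-27T13:22:10+0000,2022-01-27T13:22:10+0000,2022-01-27T13:22:10+0000,5,County19,20691,facebook_ad,TRUE,,judy.evans75@mailbox.net,410-942-1757,102 Walnut St,hshared01,14,7,the man,strongly agree,improved classroom reading district activities pickup gratitude family vaccines,c,a,d,d,a,a,b,d,a,d,d,a,d,c,b,b,b,c,b,c,no,no
R00003,survey,S00003,2022-01-27T14:13:32+0000,2022-01-27T14:13:32+0000,2022-01-27T14:13:32+0000,18.998,County23,20715,community_flyer,TRUE,,sharon.cook45@example.org,410-853-5363,103 Park St,h5b95d656,15,8,the man,strongly agree,meetings schedule support hybrid outdoor learning grades lunch guidance,a,c,d,b,a,a,c,a,b,b,a,a,d,c,a,d,a,d,d,b,yes,yes
R00004,survey,S00004,2022-01-27T14:58:06+0000,2022-01-27T14:58:06+0000,2022-01-27T14:58:06+0000,14.448,County23,20714,facebook_ad,TRUE,,daniel.davis28@mailbox.net,410-460-2139,104 Park St,h3f18bead,11,6,the man,strongly agree,protocols stress siblings community parents attendance teacher nurses virtual,a,d,b,d,b,a,d,c,a,d,c,b,c,c,d,a,a,a,a,d,yes,yes
R00005,survey,S00005,2022-01-27T15:33:23+0000,2022-01-27T15:33:23+0000,2022-01-27T15:33:23+0000,17.457,County03,20611,postcard,TRUE,,brenda.carter49@mailbox.net,410-017-5451,105 Elm St,hshared01,14,8,the man,strongly agree,teacher vaccines teachers county thankful recess wellbeing return quarantine,c,b,d,c,c,b,b,d,d,d,b,d,d,b,a,a,c,d,b,b,yes,yes
R00006,survey,S00006,2022-01-27T16:03:19+0000,2022-01-27T16:03:19+0000,2022-01-27T16:03:19+0000,18.534,County02,20608,community_flyer,TRUE,,lisa.ward38@mailbox.net,410-315-5104,106 Lake St,h6baa1ac6,8,1,the man,strongly agree,friends tutoring staff math health safety school meetings sports,d,b,b,a,b,c,a,b,a,b,c,d,d,a,a,d,d,a,a,b,yes,yes
R00007,survey,S00007,2022-01-27T16:24:30+0000,2022-01-27T16:24:30+0000,2022-01-27T16:24:30+0000,19.044,County19,20695,community_flyer,TRUE,,sean.holmes32@example.org,410-116-7987,107 River St,h6325cf94,14,8,the man,strongly agree,dropoff county difficult tutoring sports masks learning appreciated questions,c,a,c,c,c,d,a,d,c,d,b,d,a,c,a,b,c,c,d,d,no,no
R00008,survey,S00008,2022-01-27T13:35:38+0000,2022-01-27T16:35:38+0000,2022-01-27T16:35:38+0000,18.77,County08,20638,community_flyer,TRUE,,gregory.bailey27@mailbox.net,410-696-6658,108 Walnut St,h389cc569,8,1,the man,strongly agree,difficult activities classroom learning teacher math homework family staff,a,c,c,b,d,c,b,a,a,d,c,a,a,b,b,d,b,c,a,c,yes,yes
R00009,survey,S00009,2022-01-27T17:05:29+0000,2022-01-27T17:05:29+0000,2022-01-27T17:05:29+0000,17.011,County07,20632,postcard,TRUE,,sarah.ford90@example.org,410-822-1399,109 Hill St,h23d780e5,13,7,the man,strongly agree,counselors quarantine meetings projects teachers transport guidance safety answers,d,a,a,a,c,a,c,d,d,d,a,a,a,b,a,a,c,a,d,c,yes,yes
R00010,survey,S00010,2022-01-27T17:19:18+0000,2022-01-27T17:19:18+0000,2022-01-27T17:19:18+0000,17.908,County15,20674,listserv,TRUE,,julia.cook91@inbox.co,410-237-5366,110 Sunset St,h09795be0,9,2,the man,strongly agree,friends distance policy projects siblings patience communication answers homework,d,d,c,d,a,b,a,b,a,d,c,d,c,b,c,a,b,b,c,a,no,no
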