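item_id,text,n_steps,difficulty,in_pool,thresholds,routes
15,"Were you ever bothered by noise at night from other patients?",1,2.17,TRUE,,
16,"Were you ever bothered by noise at night from hospital staff?",1,1.84,TRUE,,
17,"In your opinion, how clean was the hospital room or ward that you were in?",3,-0.56,TRUE,,
18,"How clean were the toilets and bathrooms that you used in the hospital?",3,-2.20,TRUE,,
19,"Did you feel threatened during your stay in the hospital by other patients or visitors?",1,1.88,TRUE,,
20,"Were hand-wash gels available for patients and visitors to use?",2,1.33,TRUE,,
21,"How would you rate the hospital food?",3,-1.72,TRUE,,
22,"Were you offered a choice of food?",2,-0.04,TRUE,,
23,"Did you get enough help from staff to eat your meals?",2,0.98,TRUE,,
24,"When you had important questions to ask a doctor, did you get answers that you could understand?",2,-1.01,TRUE,,
25,"Did you have confidence and trust in the doctors treating you?",2,-0.86,TRUE,,
26,"Did doctors talk in front of you as if you weren't there?",2,-1.15,TRUE,,
27,"When you had important questions to ask a nurse, did you get answers that you could understand?",2,1.48,TRUE,,
28,"Did you have confidence and trust in the nurses treating you?",2,1.26,TRUE,,
29,"Did nurses talk in front of you as if you weren't there?",2,-1.46,TRUE,,
30,"In your opinion, were there enough nurses on duty to care for you in the hospital?",2,-1.40,TRUE,,
31,"Sometimes in a hospital, a member of staff will say one thing and another will say something quite different. Did this happen to you?",2,-1.22,TRUE,,
32,"Were you involved as much as you wanted to be in decisions about your care and treatment?",2,0.56,TRUE,,
33,"Did you have confidence in the decisions made about your condition or treatment?",2,-0.78,TRUE,,
34,"How much information about your condition or treatment was given to you?",2,1.48,TRUE,,
35,"Did you find someone on the hospital staff to talk to about your worries and fears?",2,-0.77,TRUE,,
36,"Do you feel you got enough emotional support from hospital staff during your stay?",2,-0.75,TRUE,,
37,"Were you given enough privacy when discussing your condition or treatment?",2,1.58,TRUE,,
38,"Were you given enough privacy when being examined or treated?",2,-0.65,TRUE,,
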