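item_id,text,n_steps,difficulty,in_pool,thresholds,routes
39,"Synthetic skip item: did you need this service? (answer 1 routes to item 40, answer 2 routes to item 41)",2,0.00,FALSE,,1:40;2:41
40,"Synthetic follow-up A, asked only after answer 1 on item 39",2,-0.50,FALSE,,
41,"Synthetic follow-up B, asked only after answer 2 on item 39",1,0.30,FALSE,,
42,"Synthetic skip item: any further concerns? (answer 0 skips ahead to item 44)",1,0.10,FALSE,,0:44
43,"Synthetic detail item reached only when item 42 is answered 1",2,0.70,FALSE,,
44,"Synthetic closing item, last in the demo questionnaire",1,-0.20,FALSE,,
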